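# Rasterise a filled disc onto a matrix; returns the pixel indices set.
render_disc <- function(dim, cx, cy, r) {
  rows <- max(1L, floor(cy - r)):min(dim[1], ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(dim[2], ceiling(cx + r))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  keep <- (rr - cy)^2 + (cc - cx)^2 <= r^2
  cbind(row = rr[keep], col = cc[keep])
}

#' Simulate a two-channel microscopy field of round cells
#'
#' Renders `n_cells` non-overlapping cells on an auto-sized canvas: the blue
#' (DAPI) channel holds one bright round nucleus per cell, the green
#' (membrane stain) channel a filled disc whose rendered pixel count is the
#' recorded truth area. Cell areas are log-normal around `median_area` with
#' log-sd `config$area_sdlog`. With `distractors = TRUE` the blue channel
#' additionally contains elongated bright bars (mitotic/dying look-alikes
#' that fail the roundness filter) and dim round nuclei (fail the intensity
#' filter); distractors carry no green signal.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_cells number of cells (default `config$n_cells`).
#' @param median_area median cell area in px (default the wt median).
#' @param distractors add elongated and dim distractor nuclei.
#' @return list with `green` and `blue` intensity matrices in [0,1], and
#'   `truth`: data.frame(cell_id, cx, cy, area_px, nucleus_area).
#' @export
gen_cell_images <- function(config = sim_config(), seed = 1,
                            n_cells = config$n_cells,
                            median_area = config$median_area_wt,
                            distractors = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (n_cells < 0) stop("n_cells must be non-negative", call. = FALSE)
  with_seed(seed, {
    n_extra <- if (distractors && n_cells > 0) max(2L, n_cells %/% 10L) else 0L
    n_slots <- n_cells + n_extra
    if (n_slots == 0) {
      return(list(green = matrix(0, 64, 64), blue = matrix(0, 64, 64),
                  truth = data.frame(cell_id = integer(), cx = numeric(),
                                     cy = numeric(), area_px = integer(),
                                     nucleus_area = integer())))
    }
    areas <- stats::rlnorm(n_cells, log(median_area), config$area_sdlog)
    radii <- sqrt(areas / pi)
    r_max <- if (n_cells) max(radii) else 20
    pitch <- ceiling(2 * r_max) + 24L
    ngrid <- ceiling(sqrt(n_slots))
    dim <- c(ngrid, ngrid) * pitch
    if (any(dim < 2 * r_max + 4))
      stop("requested cells do not fit the canvas", call. = FALSE)
    green <- matrix(stats::runif(prod(dim), 0, 0.05), dim[1], dim[2])
    blue <- matrix(stats::runif(prod(dim), 0, 0.05), dim[1], dim[2])
    grid <- expand.grid(gy = seq_len(ngrid), gx = seq_len(ngrid))
    grid <- grid[sample.int(nrow(grid), n_slots), , drop = FALSE]
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      jit <- stats::runif(2, -5, 5)
      cy <- (grid$gy[i] - 0.5) * pitch + jit[1]
      cx <- (grid$gx[i] - 0.5) * pitch + jit[2]
      px <- render_disc(dim, cx, cy, radii[i])
      green[px] <- stats::runif(nrow(px), 0.7, 0.95)
      rn <- max(3, radii[i] / 3)
      npx <- render_disc(dim, cx, cy, rn)
      blue[npx] <- stats::runif(nrow(npx), 0.85, 0.95)
      truth[[i]] <- data.frame(cell_id = i, cx = cx, cy = cy,
                               area_px = nrow(px), nucleus_area = nrow(npx))
    }
    if (n_extra > 0) {
      for (k in seq_len(n_extra)) {
        g <- grid[n_cells + k, ]
        cy <- (g$gy - 0.5) * pitch; cx <- (g$gx - 0.5) * pitch
        if (k %% 2 == 1) {  # elongated bright bar
          half_l <- 15; half_w <- 1
          rows <- round(cy - half_w):round(cy + half_w)
          cols <- round(cx - half_l):round(cx + half_l)
          blue[as.matrix(expand.grid(rows, cols))] <- 0.9
        } else {            # dim round nucleus
          npx <- render_disc(dim, cx, cy, 8)
          blue[npx] <- 0.2
        }
      }
    }
    truth <- if (n_cells) do.call(rbind, truth) else
      data.frame(cell_id = integer(), cx = numeric(), cy = numeric(),
                 area_px = integer(), nucleus_area = integer())
    list(green = green, blue = blue, truth = truth)
  })
}

#' Write / read a grayscale channel as PNG
#'
#' @param mat intensity matrix in [0,1].
#' @param path file path.
#' @return `write_channel_png` the path; `read_channel_png` a matrix.
#' @export
write_channel_png <- function(mat, path) {
  png::writePNG(pmin(pmax(mat, 0), 1), path)
  invisible(path)
}

#' @rdname write_channel_png
#' @export
read_channel_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
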