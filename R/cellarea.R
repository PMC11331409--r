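# Moore-neighbour boundary trace of one connected component.
# `px` is a 2-column matrix of (row, col) pixels. Returns the chain-code
# perimeter: axis steps count 1, diagonal steps sqrt(2). The chain-code
# length of a digitised disc is close to its true circumference, so disc
# roundness stays near 0.9 despite discretisation.
trace_perimeter <- function(px) {
  n <- nrow(px)
  if (n == 1) return(4)
  if (n == 2) return(6)
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  nr <- max(px[, 1]) - r0 + 3L; nc <- max(px[, 2]) - c0 + 3L
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- TRUE
  # clockwise Moore neighbourhood starting west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  step_w <- ifelse(dr != 0 & dc != 0, sqrt(2), 1)
  # start: topmost pixel of leftmost column; backtrack points west
  scol <- min(px[, 2]) - c0 + 2L
  srow <- min(px[px[, 2] - c0 + 2L == scol, 1]) - r0 + 2L
  cur <- c(srow, scol); back_dir <- 1L  # direction of the backtrack pixel
  per <- 0
  steps <- 0L
  first_state <- NULL  # (pixel, move direction) of the first boundary step
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- (back_dir - 1L + k) %% 8L + 1L
      nb <- c(cur[1] + dr[d], cur[2] + dc[d])
      if (m[nb[1], nb[2]]) {
        state <- c(cur, d)
        # stop when the very first (pixel, direction) step recurs: the
        # contour has then been traversed exactly once
        if (!is.null(first_state) && all(state == first_state)) {
          found <- NA
          break
        }
        if (is.null(first_state)) first_state <- state
        per <- per + step_w[d]
        # new backtrack: the last background neighbour examined, relative
        # to the pixel we move onto
        prev <- (d - 2L) %% 8L + 1L
        rel <- c(cur[1] + dr[prev] - nb[1], cur[2] + dc[prev] - nb[2])
        back_dir <- which(dr == rel[1] & dc == rel[2])
        cur <- nb
        found <- TRUE
        break
      }
    }
    steps <- steps + 1L
    if (is.na(found)) break
    if (!found) return(4)  # no traceable contour (degenerate component)
    if (steps > 8L * n + 8L) break  # safety against pathological masks
  }
  per
}

#' Detect nucleus seeds in the DAPI channel
#'
#' Thresholds the blue channel (Otsu by default), labels connected
#' components, and accepts components as nucleus seeds when they pass the
#' roundness and intensity filters that exclude dividing or dying cells:
#' roundness = 4*pi*area / perimeter^2 (chain-code perimeter, clamped to 1)
#' must reach `r_min`, and the mean intensity must reach `i_min`. Rejected
#' components stay in the output with their reason.
#'
#' @param blue grayscale matrix in [0, 1].
#' @param threshold binarisation threshold; `NULL` for Otsu.
#' @param r_min minimum roundness (default 0.8; a digitised disc scores
#'   about 0.9).
#' @param i_min minimum mean intensity.
#' @param min_area minimum component area in px (drops specks).
#' @return list of class `nucleus_seeds`: `seeds` data.frame (seed_id, row,
#'   col, area, perimeter, roundness, mean_intensity, accepted,
#'   reject_reason) and `pixels`, a list of (row, col) matrices per seed.
#' @export
detect_nuclei <- function(blue, threshold = NULL, r_min = 0.8, i_min = 0.5,
                          min_area = 20) {
  if (is.null(threshold)) {
    threshold <- tryCatch(EBImage::otsu(EBImage::Image(blue)),
                          error = function(e) NA_real_)
    if (is.na(threshold)) threshold <- 0.5
  }
  mask <- blue > threshold
  empty <- list(seeds = data.frame(seed_id = integer(), row = numeric(),
                                   col = numeric(), area = integer(),
                                   perimeter = numeric(), roundness = numeric(),
                                   mean_intensity = numeric(),
                                   accepted = logical(),
                                   reject_reason = character()),
                pixels = list())
  class(empty) <- "nucleus_seeds"
  if (!any(mask)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  nlab <- max(lab)
  idx <- which(lab > 0)
  comp <- split(idx, lab[idx])
  nr <- nrow(blue)
  seeds <- vector("list", length(comp)); pixels <- vector("list", length(comp))
  j <- 0
  for (k in seq_along(comp)) {
    ii <- comp[[k]]
    if (length(ii) < min_area) next
    j <- j + 1
    px <- cbind(row = (ii - 1L) %% nr + 1L, col = (ii - 1L) %/% nr + 1L)
    per <- trace_perimeter(px)
    area <- nrow(px)
    roundness <- min(1, 4 * pi * area / per^2)
    mi <- mean(blue[ii])
    reason <- if (roundness < r_min) "roundness"
      else if (mi < i_min) "intensity" else NA_character_
    seeds[[j]] <- data.frame(seed_id = j, row = mean(px[, 1]),
                             col = mean(px[, 2]), area = area,
                             perimeter = per, roundness = roundness,
                             mean_intensity = mi, accepted = is.na(reason),
                             reject_reason = reason)
    pixels[[j]] <- px
  }
  if (j == 0) return(empty)
  out <- list(seeds = do.call(rbind, seeds[seq_len(j)]),
              pixels = pixels[seq_len(j)])
  class(out) <- "nucleus_seeds"
  out
}

#' Grow cell regions from nucleus seeds over the membrane channel
#'
#' Simultaneous breadth-first region growing from every accepted seed over
#' 4-connected pixels whose green intensity reaches `stop_threshold`. All
#' frontiers advance one step per iteration; a pixel contested within a
#' step goes to the seed with the nearer centroid (ties to the lower seed
#' index), and once labelled a pixel is never re-assigned, so regions are
#' pairwise disjoint and each contains its seed (seed pixels are kept even
#' below the threshold).
#'
#' @param green grayscale matrix in [0, 1].
#' @param seeds a `nucleus_seeds` object (only accepted seeds are grown).
#' @param stop_threshold minimum green intensity for growth.
#' @return data.frame (seed_id, area) with the label matrix in attribute
#'   `labels`.
#' @export
grow_regions <- function(green, seeds, stop_threshold = 0.5) {
  stopifnot(inherits(seeds, "nucleus_seeds"))
  acc <- which(seeds$seeds$accepted)
  nr <- nrow(green); nc <- ncol(green)
  lab <- matrix(0L, nr, nc)
  if (length(acc)) {
    all_idx <- unlist(lapply(seeds$pixels[acc], function(px)
      (px[, 2] - 1L) * nr + px[, 1]))
    if (anyDuplicated(all_idx)) stop("overlapping seeds", call. = FALSE)
  }
  allowed <- green >= stop_threshold
  cy <- seeds$seeds$row; cx <- seeds$seeds$col
  frontier_idx <- integer(); frontier_lab <- integer()
  for (s in acc) {
    px <- seeds$pixels[[s]]
    ii <- (px[, 2] - 1L) * nr + px[, 1]
    lab[ii] <- s
    frontier_idx <- c(frontier_idx, ii)
    frontier_lab <- c(frontier_lab, rep.int(s, length(ii)))
  }
  while (length(frontier_idx)) {
    row <- (frontier_idx - 1L) %% nr + 1L
    nb_idx <- c(frontier_idx - 1L, frontier_idx + 1L,
                frontier_idx - nr, frontier_idx + nr)
    nb_lab <- rep.int(frontier_lab, 4L)
    ok <- c(row > 1L, row < nr,
            frontier_idx > nr, frontier_idx <= (nc - 1L) * nr)
    nb_idx <- nb_idx[ok]; nb_lab <- nb_lab[ok]
    keep <- allowed[nb_idx] & lab[nb_idx] == 0L
    nb_idx <- nb_idx[keep]; nb_lab <- nb_lab[keep]
    if (!length(nb_idx)) break
    # contested pixels: nearer seed centroid wins, then lower index
    prow <- (nb_idx - 1L) %% nr + 1L
    pcol <- (nb_idx - 1L) %/% nr + 1L
    d2 <- (prow - cy[nb_lab])^2 + (pcol - cx[nb_lab])^2
    o <- order(nb_idx, d2, nb_lab)
    nb_idx <- nb_idx[o]; nb_lab <- nb_lab[o]
    first <- !duplicated(nb_idx)
    nb_idx <- nb_idx[first]; nb_lab <- nb_lab[first]
    lab[nb_idx] <- nb_lab
    frontier_idx <- nb_idx; frontier_lab <- nb_lab
  }
  areas <- data.frame(seed_id = acc,
                      area = vapply(acc, function(s) sum(lab == s), 0L))
  attr(areas, "labels") <- lab
  areas
}

#' Compare cell-area distributions between two populations
#'
#' @param areas_a,areas_b numeric vectors of per-cell areas (px).
#' @return list with per-population `n`, `median`, `q1`, `q3` and
#'   `percent_difference` = 100 * (median_b / median_a - 1).
#' @export
compare_areas <- function(areas_a, areas_b) {
  if (!length(areas_a) || !length(areas_b))
    stop("both populations need at least one region", call. = FALSE)
  st <- function(x) list(n = length(x), median = stats::median(x),
                         q1 = unname(stats::quantile(x, 0.25)),
                         q3 = unname(stats::quantile(x, 0.75)))
  list(a = st(areas_a), b = st(areas_b),
       percent_difference =
         100 * (stats::median(areas_b) / stats::median(areas_a) - 1))
}
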