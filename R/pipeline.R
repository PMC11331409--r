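#' Default pipeline configuration
#'
#' Nested list of stage toggles and per-stage parameter blocks; it
#' round-trips unchanged through YAML, and [run_pipeline()] rejects unknown
#' keys.
#'
#' @return a nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "results/pipeline",
    stages = list(simulate = TRUE, editing = TRUE, annotate = TRUE,
                  translatome = TRUE, enrich = TRUE, smallrna = TRUE,
                  cellarea = TRUE),
    simulate = list(n_genes = 60L, n_sites_null = 300L, n_sites_edited = 60L,
                    n_count_genes = 800L, n_interaction = 40L,
                    interaction_l2fc = 1.5, n_smallrna = 300L,
                    n_cells = 40L),
    editing = list(threshold = 2.0, min_coverage = 5L, min_baseq = 20,
                   min_freq = 0.005, max_bg_freq = 0.001),
    translatome = list(fc = 1.5, alpha = 0.05, min_reads = 4L,
                       min_samples = 3L),
    cellarea = list(r_min = 0.8, i_min = 0.5, stop_threshold = 0.5)
  )
}

check_config <- function(config) {
  ref <- default_run_config()
  walk <- function(cfg, tmpl, path = "") {
    extra <- setdiff(names(cfg), names(tmpl))
    if (length(extra))
      stop("unknown config key(s): ",
           paste0(path, extra, collapse = ", "), call. = FALSE)
    for (k in names(cfg))
      if (is.list(tmpl[[k]])) walk(cfg[[k]], tmpl[[k]], paste0(path, k, "/"))
  }
  walk(config, ref)
  # fill defaults for missing keys
  merge <- function(cfg, tmpl) {
    for (k in names(tmpl)) {
      if (!k %in% names(cfg)) cfg[[k]] <- tmpl[[k]]
      else if (is.list(tmpl[[k]])) cfg[[k]] <- merge(cfg[[k]], tmpl[[k]])
    }
    cfg
  }
  merge(config, ref)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order — simulate, editing calls,
#' site annotation, translatome, enrichment, small RNA, cell area — each
#' drawing from its own seed stream derived from the master seed, logging
#' parameters and counts, and writing its outputs under `out_dir`. A
#' disabled stage causes its dependents to be skipped with a notice. The
#' manifest (file names and MD5 checksums) is written as JSON;
#' identical config + seed reproduce it byte-for-byte.
#'
#' @param config nested list as in [default_run_config()], or a path to a
#'   YAML file with the same structure; missing keys take their defaults,
#'   unknown keys are an error.
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- check_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "run.log"), "w")
  on.exit(close(logf))
  written <- character()
  emit <- function(path) written <<- c(written, path)
  st <- cfg$stages
  done <- list()

  if (st$simulate) {
    log_line(logf, "[simulate] n_genes=%d seed=%d", cfg$simulate$n_genes, cfg$seed)
    gm <- gen_gene_models(cfg$simulate$n_genes, derive_seed(cfg$seed, "annotation"))
    write_gene_models(gm, gtf = file.path(out, "genes.gtf"),
                      bed = file.path(out, "repeats.bed"),
                      fasta = file.path(out, "genome.fa"))
    emit(file.path(out, "genes.gtf")); emit(file.path(out, "repeats.bed"))
    emit(file.path(out, "genome.fa"))
    sc <- sim_config(n_genes = cfg$simulate$n_genes)
    spec <- plant_edit_sites(gm, n_null = cfg$simulate$n_sites_null,
                             n_wt_only = cfg$simulate$n_sites_edited,
                             n_ct = 10, seed = derive_seed(cfg$seed, "sites"))
    pu <- gen_pileups(gm, sc, spec, derive_seed(cfg$seed, "pileup"))
    write_pileup(pu$pileup, file.path(out, "pileup.tsv"))
    emit(file.path(out, "pileup.tsv"))
    ni <- cfg$simulate$n_interaction
    ids <- sprintf("gene%04d", seq_len(cfg$simulate$n_count_genes))
    eff <- data.frame(gene_id = ids[seq_len(2 * ni)],
                      interaction_l2fc = rep(c(1, -1), ni) *
                        cfg$simulate$interaction_l2fc)
    cm <- gen_count_matrix(ids, effects = eff, config = sc,
                           seed = derive_seed(cfg$seed, "counts"))
    write_tsv(cbind(gene_id = rownames(cm$counts), as.data.frame(cm$counts)),
              file.path(out, "counts.tsv"))
    write_tsv(cm$meta, file.path(out, "meta.tsv"))
    emit(file.path(out, "counts.tsv")); emit(file.path(out, "meta.tsv"))
    sr <- gen_smallrna_counts(cfg$simulate$n_smallrna, config = sc,
                              seed = derive_seed(cfg$seed, "smallrna"))
    write_tsv(cbind(feature_id = rownames(sr$counts), as.data.frame(sr$counts)),
              file.path(out, "smallrna_counts.tsv"))
    write_tsv(sr$classes, file.path(out, "smallrna_classes.tsv"))
    emit(file.path(out, "smallrna_counts.tsv"))
    emit(file.path(out, "smallrna_classes.tsv"))
    img_wt <- gen_cell_images(sc, derive_seed(cfg$seed, "images_wt"),
                              n_cells = cfg$simulate$n_cells,
                              median_area = sc$median_area_wt)
    img_ko <- gen_cell_images(sc, derive_seed(cfg$seed, "images_ko"),
                              n_cells = cfg$simulate$n_cells,
                              median_area = sc$median_area_ko)
    for (nm in c("wt", "ko")) {
      img <- get(paste0("img_", nm))
      write_channel_png(img$green, file.path(out, paste0(nm, "_green.png")))
      write_channel_png(img$blue, file.path(out, paste0(nm, "_blue.png")))
      emit(file.path(out, paste0(nm, "_green.png")))
      emit(file.path(out, paste0(nm, "_blue.png")))
    }
    done$simulate <- list(gm = gm, sc = sc, pu = pu, cm = cm, sr = sr,
                          img = list(wt = img_wt, ko = img_ko))
  } else log_line(logf, "[simulate] disabled")

  if (st$editing && !is.null(done$simulate)) {
    pu <- done$simulate$pu
    grp <- split(pu$samples$sample, pu$samples$group)[c("wt", "ko")]
    calls <- call_differential_editing(
      pu$pileup, grp, threshold = cfg$editing$threshold,
      min_coverage = cfg$editing$min_coverage,
      min_baseq = cfg$editing$min_baseq)
    s <- attr(calls, "summary")
    log_line(logf, "[editing] %d sites: %d pass, %d fail, %d filtered",
             s$n_sites, s$n_pass, s$n_fail, s$n_filtered)
    wtonly <- wt_only_filter(calls, min_freq = cfg$editing$min_freq,
                             max_bg_freq = cfg$editing$max_bg_freq)
    log_line(logf, "[editing] wt-only retained: %d", nrow(wtonly))
    write_tsv(calls, file.path(out, "editing_calls.tsv"))
    write_tsv(wtonly, file.path(out, "editing_wt_only.tsv"))
    emit(file.path(out, "editing_calls.tsv"))
    emit(file.path(out, "editing_wt_only.tsv"))
    aei <- compute_aei(pu$pileup, done$simulate$gm$repeats,
                       samples = grp$wt)
    jsonlite::write_json(
      list(summary = s[c("n_sites", "n_pass", "n_filtered")],
           n_wt_only = nrow(wtonly), aei_wt = aei),
      file.path(out, "editing_summary.json"), auto_unbox = TRUE, digits = 10)
    emit(file.path(out, "editing_summary.json"))
    done$editing <- list(calls = calls, wtonly = wtonly)
  } else if (st$editing) {
    log_line(logf, "[editing] skipped: simulate outputs missing")
  } else log_line(logf, "[editing] disabled")

  if (st$annotate && !is.null(done$editing)) {
    ann <- annotate_sites(done$editing$wtonly, done$simulate$gm)
    sm <- summarize_sites(ann)
    log_line(logf, "[annotate] %d sites in %d genes", sm$n_sites, sm$n_genes)
    write_tsv(ann, file.path(out, "sites_annotated.tsv"))
    tab <- as.data.frame(sm$table)
    write_tsv(cbind(region = rownames(sm$table), as.data.frame(sm$table)),
              file.path(out, "region_repeat_table.tsv"))
    emit(file.path(out, "sites_annotated.tsv"))
    emit(file.path(out, "region_repeat_table.tsv"))
    done$annotate <- list(ann = ann, sm = sm)
  } else if (st$annotate) {
    log_line(logf, "[annotate] skipped: editing outputs missing")
  } else log_line(logf, "[annotate] disabled")

  if (st$translatome && !is.null(done$simulate)) {
    cm <- done$simulate$cm
    counts <- filter_low_counts(cm$counts, cfg$translatome$min_reads,
                                cfg$translatome$min_samples)
    res <- nb_wald(counts, cm$meta, design = "interaction")
    cls <- classify_translation(res, fc = cfg$translatome$fc,
                                alpha = cfg$translatome$alpha)
    log_line(logf, "[translatome] %d genes tested: %d retarded, %d enhanced",
             nrow(res), sum(cls$class == "retarded"),
             sum(cls$class == "enhanced"))
    write_tsv(res, file.path(out, "translatome_de.tsv"))
    write_tsv(cls, file.path(out, "translatome_calls.tsv"))
    pca <- pca_counts(counts, cm$meta)
    write_tsv(pca, file.path(out, "pca.tsv"))
    emit(file.path(out, "translatome_de.tsv"))
    emit(file.path(out, "translatome_calls.tsv"))
    emit(file.path(out, "pca.tsv"))
    done$translatome <- list(res = res, cls = cls)
  } else if (st$translatome) {
    log_line(logf, "[translatome] skipped: simulate outputs missing")
  } else log_line(logf, "[translatome] disabled")

  if (st$enrich && !is.null(done$translatome)) {
    cls <- done$translatome$cls
    # feature: a deterministic pseudo-random subset standing in for e.g.
    # snoRNA-host membership, enriched among retarded genes by truth
    truth_eff <- done$simulate$cm$truth$effects
    feat <- data.frame(gene_id = truth_eff$gene_id,
                       flag = truth_eff$interaction_l2fc > 0)
    mb <- build_membership(cls, feat, "retarded")
    orr <- tryCatch(odds_membership(mb$in_group, mb$has_feature),
                    error = function(e) NULL)
    if (!is.null(orr)) {
      log_line(logf, "[enrich] retarded-group OR = %.3f (p = %.3g)",
               orr$odds_ratio, orr$p)
      write_tsv(data.frame(group = "retarded", feature = "planted_positive",
                           a = orr$cells["a"], b = orr$cells["b"],
                           c = orr$cells["c"], d = orr$cells["d"],
                           odds_ratio = orr$odds_ratio, p = orr$p),
                file.path(out, "enrichment.tsv"))
      emit(file.path(out, "enrichment.tsv"))
    } else log_line(logf, "[enrich] degenerate table; no output")
    done$enrich <- TRUE
  } else if (st$enrich) {
    log_line(logf, "[enrich] skipped: translatome outputs missing")
  } else log_line(logf, "[enrich] disabled")

  if (st$smallrna && !is.null(done$simulate)) {
    sr <- done$simulate$sr
    counts <- filter_low_counts(sr$counts, cfg$translatome$min_reads,
                                cfg$translatome$min_samples)
    res <- nb_wald(counts, sr$meta, design = "two_group")
    cs <- class_summary(res, sr$classes)
    log_line(logf, "[smallrna] %d features; snoRNA up=%d, RNY down=%d",
             nrow(res), cs$n_up[cs$class == "snoRNA"],
             cs$n_down[cs$class == "RNY"])
    write_tsv(cs, file.path(out, "smallrna_class_summary.tsv"))
    emit(file.path(out, "smallrna_class_summary.tsv"))
    lc <- gen_length_counts(seed = derive_seed(cfg$seed, "lengths"))
    lp <- length_profile_compare(lc$counts, lc$meta,
                                 seed = derive_seed(cfg$seed, "boot"))
    write_tsv(lp, file.path(out, "length_profile.tsv"))
    emit(file.path(out, "length_profile.tsv"))
    done$smallrna <- TRUE
  } else if (st$smallrna) {
    log_line(logf, "[smallrna] skipped: simulate outputs missing")
  } else log_line(logf, "[smallrna] disabled")

  if (st$cellarea && !is.null(done$simulate)) {
    res <- lapply(done$simulate$img, function(img) {
      seeds <- detect_nuclei(img$blue, r_min = cfg$cellarea$r_min,
                             i_min = cfg$cellarea$i_min)
      regions <- grow_regions(img$green, seeds,
                              stop_threshold = cfg$cellarea$stop_threshold)
      regions
    })
    cmp <- compare_areas(res$wt$area, res$ko$area)
    log_line(logf,
             "[cellarea] wt n=%d median=%.0f px; ko n=%d median=%.0f px; diff=%.1f%%",
             cmp$a$n, cmp$a$median, cmp$b$n, cmp$b$median,
             cmp$percent_difference)
    write_tsv(data.frame(population = c("wt", "ko"),
                         n = c(cmp$a$n, cmp$b$n),
                         median = c(cmp$a$median, cmp$b$median),
                         q1 = c(cmp$a$q1, cmp$b$q1),
                         q3 = c(cmp$a$q3, cmp$b$q3)),
              file.path(out, "cellarea_summary.tsv"))
    emit(file.path(out, "cellarea_summary.tsv"))
    done$cellarea <- TRUE
  } else if (st$cellarea) {
    log_line(logf, "[cellarea] skipped: simulate outputs missing")
  } else log_line(logf, "[cellarea] disabled")

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", digits = NA)
  log_line(logf, "[done] %d files in manifest", nrow(manifest))
  invisible(manifest)
}
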