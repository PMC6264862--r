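#' Default end-to-end run configuration
#'
#' A full run: simulate a 300-child cohort, build both representations,
#' fit the NMF rank sweep (ranks 1-8, best of 25 starts), a 3-component
#' INDSCAL and a 4-topic LDA. Model-block settings can be overridden via
#' the YAML config read by [run_pipeline()]; stages can be dropped by
#' setting their block to `NULL`.
#'
#' @param seed Global seed; per-stage seeds are derived as fixed offsets
#'   (simulation `seed`, NMF `seed + 100`, INDSCAL `seed + 200`, LDA
#'   `seed + 300`) so any stage can be re-run in isolation.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(source = "simulate", n_children = 300),
    write_diaries = FALSE,
    nmf = list(ranks = 1:8, n_starts = 25, tol = 1e-6, max_iter = 2000),
    indscal = list(R = 3, metric = "abs", n_starts = 2, tol = 1e-7,
                   max_iter = 250),
    lda = list(K = 4, eta = 0.1, alpha = 50 / 4, iterations = 1500,
               burnin = 300, thin = 10, hyper_update = TRUE)),
    class = "run_config")
}

read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = if (!is.null(raw$seed)) raw$seed else 1)
  for (block in c("cohort", "nmf", "indscal", "lda")) {
    if (block %in% names(raw)) {
      if (is.null(raw[[block]])) {
        cfg[[block]] <- NULL
      } else {
        for (key in names(raw[[block]])) {
          cfg[[block]][[key]] <- raw[[block]][[key]]
        }
      }
    }
  }
  if (!is.null(raw$write_diaries)) cfg$write_diaries <- raw$write_diaries
  cfg
}

write_table <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE, quote = FALSE)
}

tensor_to_long <- function(tensor) {
  dn <- dimnames(tensor)
  out <- expand.grid(child_id = dn[[1]], symptom = dn[[2]],
                     slot = seq_len(dim(tensor)[3]),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$year <- (out$slot - 1L) %/% 12L + 1L
  out$month <- (out$slot - 1L) %% 12L + 1L
  out$proportion <- as.vector(tensor)
  out[, c("child_id", "symptom", "year", "month", "proportion")]
}

#' Run the full diary-stratification pipeline
#'
#' Executes the requested stages in dependency order — simulate (or
#' read) the cohort, compute missingness diagnostics and inclusion,
#' build the shape and pattern representations, fit the requested models
#' — and writes every result as a CSV under `out_dir`, plus a
#' `run_manifest.yaml` recording seeds, sizes and timings. Runs are
#' deterministic given the config seed.
#'
#' @param config A `run_config` list ([default_run_config()]), or the
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = "results",
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  say <- function(...) if (!quiet) message("[diarystrat] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    val
  }

  needs_shape <- !is.null(config$nmf) || !is.null(config$indscal)
  needs_pattern <- !is.null(config$lda)

  # --- cohort -------------------------------------------------------
  if (identical(config$cohort$source, "directory")) {
    if (is.null(config$cohort$path) || !dir.exists(config$cohort$path)) {
      stop("run_pipeline: cohort source 'directory' needs an existing path")
    }
    symptoms <- config$cohort$symptoms %||% default_symptoms()
    cohort <- clock("cohort", read_cohort(config$cohort$path, symptoms))
    truth <- NULL
  } else {
    cc_args <- config$cohort[setdiff(names(config$cohort), "source")]
    cc_args$seed <- config$seed
    if (!is.null(cc_args$enrolment_window)) {
      cc_args$enrolment_window <- as.Date(cc_args$enrolment_window)
    }
    cc <- do.call(cohort_config, cc_args)
    sim <- clock("cohort", simulate_cohort(cc))
    cohort <- sim$diaries
    truth <- sim$truth
    write_table(truth$children, out_dir, "sim_truth")
    if (isTRUE(config$write_diaries)) {
      write_cohort(cohort, file.path(out_dir, "diaries"))
    }
  }
  say("cohort: ", length(cohort), " diaries")

  # --- missingness diagnostics and inclusion ------------------------
  ld <- length_distribution(cohort)
  write_table(data.frame(child_id = names(ld$counts),
                         recorded_days = as.integer(ld$counts)),
              out_dir, "length_distribution")
  write_table(missing_fraction_by_age(cohort), out_dir,
              "missing_fraction_by_age")
  bl <- suppressWarnings(burden_vs_length(cohort))
  write_table(bl$table, out_dir, "burden_vs_length")
  incl <- clock("inclusion", shape_inclusion(cohort))
  write_table(incl$children, out_dir, "inclusion")
  say("inclusion: ", incl$n_shape_included, " shape-included (",
      incl$n_complete, " complete), ", incl$n_pattern_rows,
      " pattern diary-years")
  if (needs_shape && incl$n_shape_included == 0) {
    stop("run_pipeline: no shape-included diaries; cannot fit NMF/INDSCAL")
  }
  if (needs_pattern && incl$n_pattern_rows == 0) {
    stop("run_pipeline: no pattern-included diary-years; cannot fit LDA")
  }

  # --- shape branch -------------------------------------------------
  X_hat <- NULL
  if (needs_shape) {
    tensor <- clock("tensor", suppressWarnings(build_tensor(cohort, incl)))
    write_table(tensor_to_long(tensor), out_dir, "symptom_tensor")
    # mean monthly curves over children (the seasonality display)
    mean_curves <- tensor_to_long(tensor)
    mean_curves <- stats::aggregate(
      proportion ~ symptom + year + month, data = mean_curves, FUN = mean)
    write_table(mean_curves, out_dir, "monthly_mean_curves")
    X_hat <- matricize(tensor)
    keys <- attr(X_hat, "column_keys")
    write_table(cbind(child_id = rownames(X_hat), as.data.frame(X_hat)),
                out_dir, "matricized")
  }
  if (!is.null(config$nmf)) {
    say("NMF rank sweep over ranks ",
        paste(range(config$nmf$ranks), collapse = "-"))
    sweep_res <- clock("nmf", rank_sweep(
      X_hat, ranks = config$nmf$ranks, n_starts = config$nmf$n_starts,
      seed = config$seed + 100, tol = config$nmf$tol,
      max_iter = config$nmf$max_iter))
    write_table(sweep_res$scree, out_dir, "nmf_scree")
    pick <- config$nmf$report_rank %||% 3
    pick <- min(pick, max(config$nmf$ranks))
    fit <- sweep_res$fits[[paste0("R", pick)]]
    write_table(cbind(child_id = rownames(X_hat), as.data.frame(fit$U)),
                out_dir, "nmf_scores")
    write_table(loading_table(fit, keys), out_dir, "nmf_loadings")
    say("NMF R=", pick, ": EV ",
        sprintf("%.3f", fit$explained_variance))
  }
  if (!is.null(config$indscal)) {
    say("INDSCAL R=", config$indscal$R)
    D <- clock("dissimilarity",
               build_dissimilarity(build_tensor(cohort, incl),
                                   metric = config$indscal$metric %||% "abs"))
    ifit <- clock("indscal", fit_indscal(
      D, R = config$indscal$R, n_starts = config$indscal$n_starts %||% 5,
      tol = config$indscal$tol %||% 1e-8,
      max_iter = config$indscal$max_iter %||% 500,
      seed = config$seed + 200))
    ct <- component_table(ifit)
    write_table(ct$conditions, out_dir, "indscal_conditions")
    write_table(ct$children, out_dir, "indscal_scores")
    say("INDSCAL: EV ", sprintf("%.3f", ifit$explained_variance))
  }

  # --- pattern branch -----------------------------------------------
  if (needs_pattern) {
    vocab <- clock("vocabulary", build_vocabulary(cohort, incl))
    write_table(vocab, out_dir, "pattern_vocabulary")
    F_mat <- clock("frequency", build_frequency_matrix(cohort, vocab, incl))
    write_table(cbind(diary_year = rownames(F_mat), as.data.frame(F_mat,
                check.names = FALSE)), out_dir, "frequency_matrix")
    say("pattern corpus: ", nrow(F_mat), " diary-years, ", nrow(vocab),
        " patterns")
    lcfg_args <- config$lda
    lcfg_args$seed <- config$seed + 300
    lcfg <- do.call(lda_config, lcfg_args)
    lfit <- clock("lda", fit_lda_gibbs(corpus_from_frequency(F_mat), lcfg))
    write_table(cbind(topic = rownames(lfit$beta),
                      as.data.frame(lfit$beta, check.names = FALSE)),
                out_dir, "lda_beta")
    write_table(cbind(diary_year = rownames(lfit$theta),
                      as.data.frame(lfit$theta)), out_dir, "lda_theta")
    tt <- top_terms(lfit, vocab)
    write_table(tt, out_dir, "lda_top_terms")
    topic_tab <- format_topic_table(tt)
    utils::write.csv(cbind(rank = rownames(topic_tab), topic_tab),
                     file.path(out_dir, "lda_topic_table.csv"),
                     row.names = FALSE)
    say("LDA: ", lcfg$K, " topics, final alpha ",
        sprintf("%.2f", lfit$alpha), ", eta ", sprintf("%.3f", lfit$eta))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("diarystrat")),
    r_version = R.version.string,
    seed = config$seed,
    n_diaries = length(cohort),
    stages = names(timings),
    timings_sec = timings,
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  say("done; artifacts in ", out_dir)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a summary report from persisted pipeline artifacts
#'
#' Rebuilds the standard diagnostics — missingness curve, monthly mean
#' symptom curves (split over two panels for legibility), the NMF
#' additional-explained-variance scree, INDSCAL component scatter and
#' the LDA topic table — purely from the CSV artifacts of a completed
#' [run_pipeline()] run. Sections whose artifacts are absent are
#' omitted.
#'
#' @param artifact_dir Directory written by [run_pipeline()].
#' @param out_dir Where figures and `report.md` go (default: a `report`
#'   subdirectory of `artifact_dir`).
#' @return Path to `report.md`, invisibly.
#' @export
report_run <- function(artifact_dir, out_dir = file.path(artifact_dir,
                                                         "report")) {
  has <- function(name) file.exists(file.path(artifact_dir,
                                              paste0(name, ".csv")))
  get <- function(name) utils::read.csv(file.path(artifact_dir,
                                                  paste0(name, ".csv")))
  if (!has("length_distribution")) {
    stop("report_run: no pipeline artifacts in ", artifact_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- c("# Diary stratification run report", "")
  save_fig <- function(plot, name, width = 7, height = 4.5) {
    path <- file.path(out_dir, paste0(name, ".png"))
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    md <<- c(md, paste0("![", name, "](", basename(path), ")"), "")
  }

  if (has("missing_fraction_by_age")) {
    mfa <- get("missing_fraction_by_age")
    save_fig(ggplot2::ggplot(mfa, ggplot2::aes(age, prop_missing)) +
               ggplot2::geom_line() +
               ggplot2::labs(x = "age (days since enrolment)",
                             y = "proportion missing",
                             title = "Missingness by age"),
             "missingness_by_age")
  }
  if (has("burden_vs_length")) {
    bl <- get("burden_vs_length")
    save_fig(ggplot2::ggplot(bl, ggplot2::aes(length, burden)) +
               ggplot2::geom_point(alpha = 0.5) +
               ggplot2::labs(x = "diary length (recorded days)",
                             y = "mean symptom burden",
                             title = "Burden vs dropout"),
             "burden_vs_length")
  }
  if (has("monthly_mean_curves")) {
    mc <- get("monthly_mean_curves")
    if (!"slot" %in% names(mc)) mc$slot <- (mc$year - 1) * 12 + mc$month
    syms <- sort(unique(mc$symptom))
    half <- ceiling(length(syms) / 2)
    mc$panel <- ifelse(mc$symptom %in% syms[seq_len(half)],
                       "panel 1", "panel 2")
    save_fig(ggplot2::ggplot(mc, ggplot2::aes(slot, proportion,
                                              colour = symptom)) +
               ggplot2::geom_line() +
               ggplot2::facet_wrap(~panel, ncol = 1) +
               ggplot2::labs(x = "aligned month (1-36)",
                             y = "mean monthly proportion",
                             title = "Monthly mean symptom curves"),
             "monthly_mean_curves", height = 6)
  }
  if (has("nmf_scree")) {
    sc <- get("nmf_scree")
    save_fig(ggplot2::ggplot(sc, ggplot2::aes(rank, additional_ev)) +
               ggplot2::geom_col() +
               ggplot2::labs(x = "rank", y = "additional explained variance",
                             title = "NMF scree"),
             "nmf_scree")
  }
  if (has("indscal_conditions")) {
    ic <- get("indscal_conditions")
    wide <- stats::reshape(ic, idvar = c("symptom", "year", "month"),
                           timevar = "component", direction = "wide")
    if ("weight.2" %in% names(wide)) {
      save_fig(ggplot2::ggplot(wide, ggplot2::aes(weight.1, weight.2,
                                                  colour = symptom)) +
                 ggplot2::geom_point() +
                 ggplot2::labs(x = "component 1", y = "component 2",
                               title = "INDSCAL condition weights"),
               "indscal_components")
    }
  }
  if (file.exists(file.path(artifact_dir, "lda_topic_table.csv"))) {
    tab <- utils::read.csv(file.path(artifact_dir, "lda_topic_table.csv"),
                           check.names = FALSE)
    md <- c(md, "## LDA topics", "",
            paste0("| ", paste(names(tab), collapse = " | "), " |"),
            paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
            apply(tab, 1, function(r) {
              paste0("| ", paste(r, collapse = " | "), " |")
            }), "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(file.path(out_dir, "report.md"))
}
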