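# Reproducible ensemble experiments: summary tables over (m, f) grids,
# CCDF exponent scans, and box-covering scans, with derived sub-seeds so any
# single replicate can be re-run in isolation.

MOD31 <- 2147483647

hash_chain <- function(values) {
  h <- 17
  for (v in values) h <- (h * 31 + (as.numeric(v) %% MOD31)) %% MOD31
  h
}

#' Derive a replicate sub-seed
#'
#' Deterministic 31-bit hash of `(master_seed, m, f, replicate)`, so
#' replicate r of any ensemble cell is reproducible on its own.
#'
#' @param master_seed Integer master seed.
#' @param m,f Generator parameters of the cell.
#' @param replicate Replicate index (>= 1).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, m, f, replicate) {
  h <- hash_chain(c(master_seed, m, round(f * 1e6), replicate))
  as.integer(h %% (MOD31 - 1) + 1)
}

#' Specify an FPA ensemble experiment
#'
#' @param n Nodes per network.
#' @param m_list,f_list Generator parameter grids.
#' @param replicates Networks per (m, f) cell.
#' @param master_seed Master seed; per-cell sub-seeds come from
#'   [derive_seed()].
#' @param out_dir Optional directory for CSV/JSON outputs; `NULL` keeps
#'   results in memory only.
#' @param preset `"paper"` (N = 100000, 10 replicates) or `"desk"`
#'   (N = 30000, 5 replicates) overrides `n` and `replicates`.
#' @param kmin,tail_min_count,min_class Fit options, see
#'   [fit_ccdf_exponent()] and [fit_alpha()].
#' @param n_rep_boxes Seed sequences per r in [run_fractal_scan()].
#' @param n_samples BFS sample size for path lengths of large non-tree
#'   networks.
#' @return A list of class `fpa_ensemble_spec`.
#' @export
ensemble_spec <- function(n = 30000L, m_list = 1L,
                          f_list = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                          replicates = 5L, master_seed = 1L, out_dir = NULL,
                          preset = NULL, kmin = NULL, tail_min_count = 10L,
                          min_class = 1L, n_rep_boxes = 10L,
                          n_samples = 1000L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper", "desk"))
    if (preset == "paper") { n <- 100000L; replicates <- 10L }
    else { n <- 30000L; replicates <- 5L }
  }
  stopifnot(replicates >= 1, all(f_list > 0 & f_list <= 1), all(m_list >= 1))
  structure(list(n = as.integer(n), m_list = as.integer(m_list),
                 f_list = as.numeric(f_list),
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed), out_dir = out_dir,
                 kmin = kmin, tail_min_count = as.integer(tail_min_count),
                 min_class = as.integer(min_class),
                 n_rep_boxes = as.integer(n_rep_boxes),
                 n_samples = as.integer(n_samples)),
            class = "fpa_ensemble_spec")
}

#' Read an ensemble specification from a YAML file
#'
#' The YAML keys mirror the arguments of [ensemble_spec()].
#'
#' @param path Path to a YAML file.
#' @return An `fpa_ensemble_spec`.
#' @export
ensemble_spec_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as a boolean; restore the field name
  names(vals)[names(vals) %in% c("FALSE", "no")] <- "n"
  do.call(ensemble_spec, vals)
}

spec_hash <- function(spec) {
  fields <- c(spec$n, spec$m_list, round(spec$f_list * 1e6),
              spec$replicates, spec$master_seed,
              if (is.null(spec$kmin)) -1 else spec$kmin,
              spec$tail_min_count, spec$min_class,
              spec$n_rep_boxes, spec$n_samples)
  sprintf("%08x", hash_chain(fields))
}

write_csv_with_meta <- function(df, path, spec, extra = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# fpanet ensemble output, spec_hash=%s", spec_hash(spec)),
               sprintf("# n=%d replicates=%d master_seed=%d",
                       spec$n, spec$replicates, spec$master_seed),
               extra), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

cell_networks <- function(spec, m, f) {
  lapply(seq_len(spec$replicates), function(r) {
    fpa_network(spec$n, m = m, f = f,
                seed = derive_seed(spec$master_seed, m, f, r))
  })
}

cell_seeds <- function(spec, m, f) {
  vapply(seq_len(spec$replicates),
         function(r) derive_seed(spec$master_seed, m, f, r), integer(1))
}

agg <- function(x) c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0)

#' Run a topology-summary table over an (m, f) grid
#'
#' For every cell, generates `replicates` networks from derived sub-seeds,
#' summarises each with [topology_summary()], and aggregates mean and
#' standard deviation per statistic (columns in the order: f, alpha, rho,
#' mean degree, diameter, path length, kmax, beta). A failing replicate
#' aborts only its own cell, with a message.
#'
#' @param spec An `fpa_ensemble_spec`.
#' @return A list with `table` (aggregated rows) and `replicates` (the
#'   per-replicate detail). With `out_dir` set, writes
#'   `table_summary.csv` and `table_replicates.csv` carrying the spec hash
#'   and the per-cell sub-seeds.
#' @export
run_table2 <- function(spec) {
  stopifnot(inherits(spec, "fpa_ensemble_spec"))
  rows <- list(); reps <- list()
  for (m in spec$m_list) for (f in spec$f_list) {
    seeds <- cell_seeds(spec, m, f)
    cell <- tryCatch({
      lapply(seq_len(spec$replicates), function(r) {
        net <- fpa_network(spec$n, m = m, f = f, seed = seeds[r])
        s <- topology_summary(net, kmin = spec$kmin,
                              tail_min_count = spec$tail_min_count,
                              min_class = spec$min_class,
                              n_samples = spec$n_samples)
        message(sprintf("table: m=%g f=%g replicate %d/%d done",
                        m, f, r, spec$replicates))
        cbind(as.data.frame(s), replicate = r, sub_seed = seeds[r])
      })
    }, error = function(e) {
      message(sprintf("table: cell m=%g f=%g failed: %s",
                      m, f, conditionMessage(e)))
      NULL
    })
    if (is.null(cell)) next
    det <- do.call(rbind, cell)
    reps[[length(reps) + 1L]] <- det
    stat <- vapply(c("alpha", "rho", "mean_degree", "diameter", "avg_path",
                     "kmax", "beta"),
                   function(col) agg(det[[col]]), numeric(2))
    row <- data.frame(m = m, f = f, t(as.vector(stat)))
    names(row)[-(1:2)] <- as.vector(rbind(colnames(stat),
                                          paste0(colnames(stat), "_sd")))
    row$sub_seeds <- paste(seeds, collapse = ";")
    rows[[length(rows) + 1L]] <- row
  }
  out <- list(table = do.call(rbind, rows), replicates = do.call(rbind, reps))
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_with_meta(out$table,
                        file.path(spec$out_dir, "table_summary.csv"), spec)
    write_csv_with_meta(out$replicates,
                        file.path(spec$out_dir, "table_replicates.csv"), spec)
  }
  out
}

#' Scan CCDF exponents over an (m, f) grid
#'
#' Per cell: each replicate's fitted beta, their ensemble mean and standard
#' deviation, the implied density exponent gamma = beta + 1, the deviation
#' of beta from f + 1, and the pooled cumulative distribution (all
#' replicates' degrees together).
#'
#' @inheritParams run_table2
#' @return A list with `fits` and `curves` data frames; with `out_dir` set,
#'   writes `beta_fits.csv` and `beta_curves.csv`.
#' @export
run_beta_scan <- function(spec) {
  stopifnot(inherits(spec, "fpa_ensemble_spec"))
  fits <- list(); curves <- list()
  for (m in spec$m_list) for (f in spec$f_list) {
    seeds <- cell_seeds(spec, m, f)
    cell <- tryCatch({
      nets <- cell_networks(spec, m, f)
      betas <- vapply(nets, function(net) {
        fit_ccdf_exponent(net, kmin = spec$kmin,
                          tail_min_count = spec$tail_min_count)$exponent
      }, numeric(1))
      deg_all <- unlist(lapply(nets, `[[`, "degree"))
      kv <- sort(unique(deg_all))
      cnt <- as.integer(table(factor(deg_all, levels = kv)))
      pooled <- data.frame(k = kv, pdf = cnt / length(deg_all),
                           cdf = rev(cumsum(rev(cnt))) / length(deg_all))
      list(betas = betas, pooled = pooled)
    }, error = function(e) {
      message(sprintf("betascan: cell m=%g f=%g failed: %s",
                      m, f, conditionMessage(e)))
      NULL
    })
    if (is.null(cell)) next
    message(sprintf("betascan: m=%g f=%g beta=%.3f", m, f, mean(cell$betas)))
    fits[[length(fits) + 1L]] <- data.frame(
      m = m, f = f, beta_mean = mean(cell$betas),
      beta_sd = if (spec$replicates > 1L) sd(cell$betas) else 0,
      gamma_mean = mean(cell$betas) + 1,
      beta_dev_from_f1 = abs(mean(cell$betas) - (f + 1)),
      sub_seeds = paste(seeds, collapse = ";"))
    curves[[length(curves) + 1L]] <- cbind(m = m, f = f, cell$pooled)
  }
  out <- list(fits = do.call(rbind, fits), curves = do.call(rbind, curves))
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_with_meta(out$fits, file.path(spec$out_dir, "beta_fits.csv"),
                        spec)
    write_csv_with_meta(out$curves, file.path(spec$out_dir, "beta_curves.csv"),
                        spec)
  }
  out
}

#' Scan box-covering curves over an (m, f) grid
#'
#' Per cell, covers the first-replicate network with `n_rep_boxes` seed
#' sequences per r, fits both decay models and records the verdict; warns if
#' any FPA cell does not come out non-fractal.
#'
#' @inheritParams run_table2
#' @return A list with `verdicts` (one row per cell, both fits' parameters)
#'   and `curves`; with `out_dir` set, writes `boxcover_curves.csv` and
#'   `fractal_verdicts.json`.
#' @export
run_fractal_scan <- function(spec) {
  stopifnot(inherits(spec, "fpa_ensemble_spec"))
  verdicts <- list(); curves <- list()
  for (m in spec$m_list) for (f in spec$f_list) {
    seed <- derive_seed(spec$master_seed, m, f, 1L)
    cell <- tryCatch({
      net <- fpa_network(spec$n, m = m, f = f, seed = seed)
      curve <- box_cover_curve(net, n_rep = spec$n_rep_boxes)
      list(curve = curve, cls = classify_fractality(curve))
    }, error = function(e) {
      message(sprintf("fracscan: cell m=%g f=%g failed: %s",
                      m, f, conditionMessage(e)))
      NULL
    })
    if (is.null(cell)) next
    message(sprintf("fracscan: m=%g f=%g verdict=%s", m, f,
                    cell$cls$verdict))
    verdicts[[length(verdicts) + 1L]] <- data.frame(
      m = m, f = f, verdict = cell$cls$verdict,
      exp_a = cell$cls$exponential$a, exp_b = cell$cls$exponential$b,
      exp_r2 = cell$cls$exponential$r_squared,
      pow_a = cell$cls$power$a, pow_df = cell$cls$power$df,
      pow_r2 = cell$cls$power$r_squared, sub_seed = seed)
    curves[[length(curves) + 1L]] <-
      cbind(m = m, f = f, as.data.frame(cell$curve))
  }
  out <- list(verdicts = do.call(rbind, verdicts),
              curves = do.call(rbind, curves))
  if (!all(out$verdicts$verdict == "non-fractal"))
    warning("not every cell classified non-fractal; inspect the curves")
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_with_meta(out$curves,
                        file.path(spec$out_dir, "boxcover_curves.csv"), spec)
    jsonlite::write_json(
      c(list(spec_hash = spec_hash(spec)),
        split(out$verdicts, seq_len(nrow(out$verdicts)))),
      file.path(spec$out_dir, "fractal_verdicts.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
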