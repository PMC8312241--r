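# Monte-Carlo harness: per-replicate fits, scenario-level aggregation of
# type-I error / power / bias / SE, and resumable scenario grids.

#' Wilson 95\% binomial confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return Named vector \code{c(lower, upper)}.
#' @export
binom_wilson <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, mid - half), upper = min(1, mid + half))
}

# one half gets the exposure regressions, the other the outcome
# regressions, after a seeded permutation: the two-sample device used to
# feed the summary-statistic baselines from one-sample data
split_marginals <- function(dat) {
  n <- length(dat$exposure)
  perm <- sample.int(n)
  h1 <- perm[seq_len(n %/% 2)]
  h2 <- perm[(n %/% 2 + 1):n]
  G1 <- center_columns(dat$genotypes$values[h1, , drop = FALSE])
  G2 <- center_columns(dat$genotypes$values[h2, , drop = FALSE])
  if (any(colSums(G1^2) == 0) || any(colSums(G2^2) == 0)) {
    stop("monomorphic variant within a split half")
  }
  ex <- marginal_single(G1, dat$exposure[h1] - mean(dat$exposure[h1]))
  out <- marginal_single(G2, dat$outcome[h2] - mean(dat$outcome[h2]))
  structure(list(gamma_tilde = ex$slope, Gamma_tilde = out$slope,
                 se_Gamma_tilde = out$se, se_gamma_tilde = ex$se,
                 n = length(h2), m = ncol(G1),
                 variant_ids = dat$genotypes$variant_ids),
            class = "mr_marginal_coefs")
}

#' Run one simulation replicate
#'
#' Simulates one dataset from the scenario and fits the requested methods.
#' The individual-data methods (pldmr, pldmr_t, pldmr_a, ldmr) use the full
#' sample; the summary baselines (egger, ivw) see marginal statistics from
#' a two-half split after a seeded permutation (exposure regressions from
#' one half, outcome regressions from the other). Per-method failures are
#' caught and recorded; the replicate continues.
#'
#' @param cfg an [mr_scenario()].
#' @param rep replicate index.
#' @param methods character vector from \code{c("pldmr", "pldmr_t",
#'   "pldmr_a", "ldmr", "egger", "ivw")}.
#' @return A \code{data.frame}, one row per method: \code{rep},
#'   \code{method}, \code{beta_hat}, \code{se_beta}, \code{t_stat},
#'   \code{p_value}, \code{mu_alpha_hat}, \code{r2_hat}, \code{converged},
#'   \code{error}.
#' @export
run_replicate <- function(cfg, rep = 1L, methods = c("pldmr", "ldmr")) {
  methods <- match.arg(methods, mr_fit_methods, several.ok = TRUE)
  dat <- simulate_mr_data(cfg, rep)
  jc <- NULL
  mc <- NULL
  vc_true <- variance_components(cfg$mu_alpha, cfg$sigma_alpha^2, cfg$sigma_y^2)
  P <- phenotype_pair(dat$exposure, dat$outcome)
  rows <- lapply(methods, function(meth) {
    fit <- tryCatch({
      if (meth %in% c("egger", "ivw")) {
        if (is.null(mc)) mc <<- split_marginals(dat)
        if (meth == "egger") fit_mr_egger(mc) else fit_ivw(mc)
      } else {
        if (is.null(jc)) jc <<- joint_coefs(dat$genotypes, P)
        switch(meth,
               pldmr = fit_pldmr(NULL, NULL, jc = jc),
               pldmr_t = fit_pldmr_t(NULL, NULL, vc_true, jc = jc),
               pldmr_a = fit_pldmr_a(jc),
               ldmr = fit_ldmr(NULL, NULL, jc = jc))
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(rep = rep, method = meth, beta_hat = NA_real_,
                 se_beta = NA_real_, t_stat = NA_real_, p_value = NA_real_,
                 mu_alpha_hat = NA_real_, r2_hat = NA_real_,
                 converged = FALSE, error = conditionMessage(fit),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(rep = rep, method = meth, beta_hat = fit$beta_hat,
                 se_beta = fit$se_beta, t_stat = fit$t_stat,
                 p_value = fit$p_value, mu_alpha_hat = fit$mu_alpha_hat,
                 r2_hat = fit$r2_hat, converged = fit$converged,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Run a full Monte-Carlo scenario
#'
#' Aggregates [run_replicate()] over \code{cfg$n_reps} replicates:
#' per-method rejection rate at the nominal level (with its binomial
#' Monte-Carlo standard error), mean estimate, empirical SE of the
#' estimates, mean model-based SE, and the count of failed replicates
#' (excluded from the aggregates, never silently dropped).
#'
#' @inheritParams run_replicate
#' @param keep_records keep the per-replicate fit table (default TRUE).
#' @return An object of class \code{"mr_experiment"}: list with
#'   \code{scenario}, \code{per_method} (summary \code{data.frame}),
#'   \code{wall_reps}, and optionally \code{records}.
#' @export
run_scenario <- function(cfg, methods = c("pldmr", "ldmr"),
                         keep_records = TRUE) {
  stopifnot(inherits(cfg, "mr_scenario"), cfg$n_reps >= 1)
  recs <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    recs[[r]] <- run_replicate(cfg, r, methods)
  }
  records <- do.call(rbind, recs)
  per_method <- do.call(rbind, lapply(methods, function(meth) {
    sub <- records[records$method == meth, , drop = FALSE]
    ok <- sub[!is.na(sub$beta_hat), , drop = FALSE]
    n_ok <- nrow(ok)
    rr <- if (n_ok) mean(ok$p_value < cfg$alpha_level) else NA_real_
    data.frame(method = meth,
               rejection_rate = rr,
               rejection_mc_se = if (n_ok) sqrt(rr * (1 - rr) / n_ok) else NA_real_,
               mean_beta_hat = if (n_ok) mean(ok$beta_hat) else NA_real_,
               empirical_se = if (n_ok > 1) stats::sd(ok$beta_hat) else NA_real_,
               mean_model_se = if (n_ok) mean(ok$se_beta) else NA_real_,
               n_failed = nrow(sub) - n_ok,
               stringsAsFactors = FALSE)
  }))
  out <- list(scenario = cfg, per_method = per_method,
              wall_reps = cfg$n_reps)
  if (keep_records) out$records <- records
  structure(out, class = "mr_experiment")
}

#' @export
print.mr_experiment <- function(x, digits = 4, ...) {
  s <- x$scenario
  cat(sprintf("mr_experiment: %d replicates of n=%d m=%d rho_g=%g mu_alpha=%g beta=%g\n",
              x$wall_reps, s$n, s$m, s$rho_g, s$mu_alpha, s$beta))
  print(format(x$per_method, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Bar plot of rejection rates by method
#'
#' @param x an \code{mr_experiment}.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mr_experiment <- function(x, ...) {
  pm <- x$per_method
  bp <- graphics::barplot(pm$rejection_rate,
                          names.arg = mr_fit_labels[pm$method],
                          ylab = "rejection rate",
                          main = sprintf("beta = %g, n = %d, m = %d",
                                         x$scenario$beta, x$scenario$n,
                                         x$scenario$m), ...)
  graphics::abline(h = x$scenario$alpha_level, col = "red", lty = 2)
  invisible(bp)
}

# canonical scenario digest used for resumable grids and output naming
scenario_key <- function(cfg) {
  fields <- c("n", "m", "rho_g", "mu_alpha", "sigma_alpha", "beta", "sigma_x",
              "sigma_y", "rho", "maf_low", "maf_high", "gamma_low",
              "gamma_high", "n_reps", "seed", "alpha_level", "redraw_effects")
  s <- paste(vapply(fields, function(f) sprintf("%s=%.15g", f, as.numeric(cfg[[f]])),
                    character(1)), collapse = ";")
  # polynomial rolling hash mod 2^31-1 over the canonical string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x%04x", as.integer(h), nchar(s))
}

#' Run a grid of scenarios, resumably
#'
#' Runs every scenario and writes one tidy TSV row per (scenario, method).
#' If the output file already exists, completed (scenario, method) rows —
#' identified by a stable digest of the canonicalized configuration — are
#' skipped, so an interrupted grid resumes where it stopped and re-running
#' a finished grid is a no-op.
#'
#' @param scenarios list of [mr_scenario()] objects.
#' @param methods methods to fit in every scenario.
#' @param path output TSV path.
#' @param verbose print per-scenario timing.
#' @return The grid table (invisibly), one row per scenario and method.
#' @export
run_grid <- function(scenarios, methods = c("pldmr", "ldmr"),
                     path = "grid_results.tsv", verbose = TRUE) {
  if (!length(scenarios)) stop("empty scenario list")
  done <- character(0)
  if (file.exists(path)) {
    prev <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    done <- paste(prev$scenario_key, prev$method)
  }
  scen_cols <- c("n", "m", "rho_g", "mu_alpha", "sigma_alpha", "beta",
                 "n_reps", "seed", "alpha_level")
  for (cfg in scenarios) {
    key <- scenario_key(cfg)
    todo <- methods[!(paste(key, methods) %in% done)]
    if (!length(todo)) next
    t0 <- proc.time()[["elapsed"]]
    res <- run_scenario(cfg, todo, keep_records = FALSE)
    rows <- cbind(data.frame(scenario_key = key, stringsAsFactors = FALSE),
                  as.data.frame(unclass(cfg)[scen_cols]), res$per_method)
    write_header <- !file.exists(path)
    out <- rows
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = write_header,
                       append = !write_header)
    if (verbose) {
      message(sprintf("scenario %s: %d method(s) in %.1fs", key, length(todo),
                      proc.time()[["elapsed"]] - t0))
    }
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  invisible(tab)
}

#' Expand a factorial scenario grid
#'
#' Crosses the supplied parameter vectors (anything [mr_scenario()]
#' accepts) into a list of scenarios; scalar arguments are held fixed.
#'
#' @param ... named vectors of scenario parameters.
#' @return A list of \code{mr_scenario} objects.
#' @examples
#' g <- scenario_grid(n = c(1000, 5000), mu_alpha = c(0, 0.1), n_reps = 10)
#' length(g)
#' @export
scenario_grid <- function(...) {
  args <- list(...)
  grid <- do.call(expand.grid, c(args[lengths(args) > 0],
                                 list(KEEP.OUT.ATTRS = FALSE)))
  lapply(seq_len(nrow(grid)), function(i) do.call(mr_scenario, as.list(grid[i, ])))
}
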