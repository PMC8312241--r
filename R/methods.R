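# S3 methods and serialization for mr_fit objects.

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s causal-effect estimate\n", x$label))
  cat(sprintf("  beta_hat = %s  (SE %s, %g%% CI [%s, %s])\n",
              format(x$beta_hat, digits = digits),
              format(x$se_beta, digits = digits), 100 * x$level,
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits)))
  cat(sprintf("  t = %s on %s df, p = %s  (H0: beta = %g)\n",
              format(x$t_stat, digits = digits), format(x$df),
              format.pval(x$p_value, digits = digits), x$beta0))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  extra <- c(mu_alpha_hat = f$mu_alpha_hat, r2_hat = f$r2_hat,
             sigma_y2_hat = f$sigma_y2_hat, overdispersion = f$overdispersion,
             nll_at_optimum = f$nll_at_optimum)
  extra <- extra[!is.na(extra)]
  if (length(extra)) {
    cat("  auxiliary estimates:\n")
    for (nm in names(extra)) {
      cat(sprintf("    %-15s %s\n", nm, format(extra[[nm]], digits = digits)))
    }
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  co <- c(beta = object$beta_hat)
  if (!is.na(object$mu_alpha_hat)) co <- c(mu_alpha = object$mu_alpha_hat, co)
  co
}

#' @export
vcov.mr_fit <- function(object, ...) {
  matrix(object$se_beta^2, 1, 1, dimnames = list("beta", "beta"))
}

#' @export
confint.mr_fit <- function(object, parm = "beta", level = NULL, ...) {
  if (!is.null(level) && level != object$level) {
    inf <- t_inference(object$beta_hat, object$se_beta, object$df,
                       beta0 = object$beta0, level = level)
    ci <- c(inf$ci_low, inf$ci_high)
  } else {
    level <- object$level
    ci <- c(object$ci_low, object$ci_high)
  }
  out <- matrix(ci, 1, 2,
                dimnames = list("beta", sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))))
  out
}

#' @export
logLik.mr_fit <- function(object, ...) {
  if (is.na(object$nll_at_optimum)) {
    stop("log-likelihood is only defined for the PLDMR maximum-likelihood fit")
  }
  structure(-object$nll_at_optimum, df = 4L, class = "logLik")
}

#' Residuals of the instrument-level regression
#'
#' For the joint-coefficient methods, \eqn{\hat\Gamma - \hat\mu_\alpha 1 -
#' \hat\beta\hat\gamma}; for the marginal methods the analogue with
#' \eqn{\tilde\Gamma,\tilde\gamma} (IVW has no intercept).
#'
#' @param object an \code{mr_fit}.
#' @param ... unused.
#' @export
residuals.mr_fit <- function(object, ...) {
  mu <- if (is.na(object$mu_alpha_hat)) 0 else object$mu_alpha_hat
  if (!is.null(object$jc)) {
    r <- object$jc$Gamma_hat - mu - object$beta_hat * object$jc$gamma_hat
    names(r) <- object$jc$variant_ids
  } else if (!is.null(object$mc)) {
    r <- object$mc$Gamma_tilde - mu - object$beta_hat * object$mc$gamma_tilde
    names(r) <- object$mc$variant_ids
  } else {
    stop("fit carries no instrument-level coefficients")
  }
  r
}

#' Scatter plot of instrument effects with the fitted causal line
#'
#' Plots outcome coefficients against exposure coefficients (joint
#' coefficients for the individual-data methods, marginal for MR-Egger and
#' IVW) and overlays the fitted intercept/slope line.
#'
#' @param x an \code{mr_fit}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  if (!is.null(x$jc)) {
    gx <- x$jc$gamma_hat; gy <- x$jc$Gamma_hat
    xl <- "joint exposure coefficient"; yl <- "joint outcome coefficient"
  } else {
    gx <- x$mc$gamma_tilde; gy <- x$mc$Gamma_tilde
    xl <- "marginal exposure coefficient"; yl <- "marginal outcome coefficient"
  }
  graphics::plot(gx, gy, xlab = xl, ylab = yl,
                 main = sprintf("%s: beta_hat = %.4g", x$label, x$beta_hat), ...)
  mu <- if (is.na(x$mu_alpha_hat)) 0 else x$mu_alpha_hat
  graphics::abline(a = mu, b = x$beta_hat, col = "red")
  invisible(x)
}

mr_fit_record_fields <- c("method", "beta_hat", "se_beta", "mu_alpha_hat",
                          "r2_hat", "sigma_y2_hat", "overdispersion", "df",
                          "t_stat", "p_value", "ci_low", "ci_high",
                          "converged", "nll_at_optimum")

#' Flatten a fit to a one-row record
#'
#' Deterministic field order, suitable for JSON or TSV serialization.
#'
#' @param fit an \code{mr_fit}.
#' @return A one-row \code{data.frame} with the \code{MRFit} fields.
#' @export
mr_fit_record <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  vals <- lapply(mr_fit_record_fields, function(f) {
    v <- fit[[f]]
    if (f == "method") fit$label else v
  })
  names(vals) <- mr_fit_record_fields
  as.data.frame(vals, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) mr_fit_record(x)

#' Write fit records to JSON or TSV
#'
#' @param fits an \code{mr_fit} or list of them.
#' @param path output file path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_mr_fits <- function(fits, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, mr_fit_record))
  if (format == "json") {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write_tsv17(tab, path)
  }
  invisible(path)
}
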