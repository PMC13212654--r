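#' Screen two-way interactions between the primary parameters
#'
#' Augments the log-scale mean with one product term at a time --
#' `log(W) * T`, `log(W) * U`, or `T * U` added inside the exponential, so the
#' candidate mean is `(a + u_i) W^b c^T d^U exp(g z)` -- refits by maximum
#' likelihood, and reports the log-likelihood gain, the 1-df likelihood-ratio
#' p-value and the AIC change for each candidate.
#'
#' Retention rule: a candidate is supported when `p < alpha` and
#' `deltaAIC < -2`. If more than one candidate is supported, one is retained
#' only when it is a clear winner (its AIC at least 2 below the runner-up's);
#' otherwise none is retained, since without a clear statistical winner there
#' is no basis for choosing among the product terms.
#'
#' @param ds The `respirometry` dataset the base model was fitted to.
#' @param base A converged `mo2_fit` for the interaction-free model.
#' @param alpha Significance level for the likelihood-ratio test (default
#'   0.05).
#' @return A list of class `mo2_interactions` with `candidates` (data frame:
#'   `candidate`, `delta_loglik`, `p_value`, `delta_aic`, `evaluable`) and
#'   `retained` (character, possibly empty).
#' @export
screen_interactions <- function(ds, base, alpha = 0.05) {
  stopifnot(inherits(base, "mo2_fit"))
  if (!base$converged) stop("base fit has not converged", call. = FALSE)
  candidates <- c("lnW:T", "lnW:U", "T:U")
  co <- unclass(base$coefficients)
  rows <- lapply(candidates, function(cand) {
    groups <- prepare_groups(ds, interaction = cand)
    res <- tryCatch(
      fit_ml_engine(groups, co[["a"]], co[["b"]], log(co[["c"]]),
                    log(co[["d"]]), g0 = 0,
                    su0 = max(base$sigma_study, 1e-6 * co[["a"]]),
                    sr0 = base$sigma_resid,
                    fix_su = base$fix_sigma_study0),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      return(data.frame(candidate = cand, delta_loglik = NA_real_,
                        p_value = NA_real_, delta_aic = NA_real_,
                        evaluable = FALSE))
    }
    dll <- res$loglik - base$loglik
    lrt <- max(0, 2 * dll)
    data.frame(candidate = cand, delta_loglik = dll,
               p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
               delta_aic = 2 - 2 * dll, evaluable = TRUE)
  })
  tab <- do.call(rbind, rows)
  passing <- tab[tab$evaluable & tab$p_value < alpha & tab$delta_aic < -2, ]
  retained <- character()
  if (nrow(passing) == 1L) {
    retained <- passing$candidate
  } else if (nrow(passing) > 1L) {
    ord <- passing[order(passing$delta_aic), ]
    if (ord$delta_aic[1] <= ord$delta_aic[2] - 2) retained <- ord$candidate[1]
  }
  structure(list(candidates = tab, retained = retained, alpha = alpha),
            class = "mo2_interactions")
}

#' @export
print.mo2_interactions <- function(x, ...) {
  print(x$candidates, row.names = FALSE)
  cat("retained:", if (length(x$retained)) x$retained else "(none)", "\n")
  invisible(x)
}
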