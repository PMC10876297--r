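# Internal helpers shared across modules.

#' mrscreen: two-sample Mendelian randomization screening
#'
#' Instrument selection, harmonization, causal estimators, MR-PRESSO,
#' sensitivity diagnostics, a synthetic GWAS summary-data generator and a
#' screening pipeline. See the methods vignette for the modelling details.
#'
#' @keywords internal
"_PACKAGE"

# 97.5% normal quantile used for all 95% CIs (exp() of the bounds gives ORs).
Z975 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Two-sided normal p-value for z = beta/se; clamped into (0, 1].
z_pval <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmax(p, .Machine$double.xmin)
}

# Numeric chromosome for ordering; non-numeric labels sort after numeric ones.
chrom_order <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  n[is.na(n)] <- Inf
  n
}

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(x) unname(DNA_COMPLEMENT[x])

is_palindromic <- function(a1, a2) complement_allele(a1) == a2
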