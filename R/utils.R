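#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef complete.cases cor cor.test fft lm model.matrix
#'   p.adjust pnorm pt qt quantile rbinom rnorm runif sd setNames t.test var
#'   wilcox.test residuals
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every stochastic stage reproducible
# from an explicit integer without clobbering the session RNG.
with_seed <- function(seed, expr) {
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
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a top-level seed and a stage offset; stays within
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 7919) %% 2147483629)
}

log_info <- function(...) {
  if (isTRUE(getOption("longconn.verbose", FALSE))) {
    message("[longconn] ", sprintf(...))
  }
  invisible(NULL)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

# Locale-independent numeric formatting for all text output.
fmt_num <- function(x, digits = 10) {
  formatC(x, digits = digits, format = "g")
}
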