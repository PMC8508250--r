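#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map2 imap list_rbind
#' @importFrom stats glm binomial coef vcov pchisq pnorm qnorm rnorm runif
#'   rbinom rexp rlnorm sd var median quantile cor complete.cases plogis
#'   setNames logLik anova predict
#' @importFrom utils head write.csv read.csv
NULL

# Deterministic 31-bit child seed from a parent seed, a component label and an
# index, so each pipeline stage has its own reproducible stream.
child_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) %% 65011 * 31627 + h * 2713 + index * 97 + 12345) %%
               2147483629)
}

`%g0%` <- function(x, default) if (length(x) == 0L || all(is.na(x))) default else x

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name),
          class = "edrisk_config_error")
  }
  invisible(x)
}
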