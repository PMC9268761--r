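# internal helpers: classed error conditions and seeded evaluation

abort_format <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("markerdiv_format_error",
                                     "markerdiv_error", "error", "condition")))
}

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("markerdiv_validation_error",
                                     "markerdiv_error", "error", "condition")))
}

abort_lookup <- function(msg) {
  stop(errorCondition(msg, class = c("markerdiv_lookup_error",
                                     "markerdiv_error", "error", "condition")))
}

abort_argument <- function(msg) {
  stop(errorCondition(msg, class = c("markerdiv_argument_error",
                                     "markerdiv_error", "error", "condition")))
}

# evaluate expr under a fixed seed, restoring the caller's RNG state after;
# keeps generators deterministic without clobbering the session stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# round half up at `digits` decimals; base round() rounds half to even, which
# is not the convention the printed percentages follow
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# format a branch length: integral heights render with one decimal ("1.0"),
# others at full precision with trailing zeros trimmed
format_blen <- function(x) {
  ifelse(abs(x - round(x)) < 1e-12,
         sprintf("%.1f", x),
         sub("0+$", "", sprintf("%.10f", x)))
}
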