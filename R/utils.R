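# Internal numerical and control-flow helpers shared across the package.

# Linear predictors are clipped to +/- ETA_CLIP before exponentiation so that
# exp() never overflows; plogis/pnorm are already saturated well inside this
# range, so the clip does not change any probability at double precision.
ETA_CLIP <- 35

clip_eta <- function(eta) pmin(pmax(eta, -ETA_CLIP), ETA_CLIP)

#' @keywords internal
link_inverse <- function(link) {
  switch(link,
    logit = function(eta) stats::plogis(clip_eta(eta)),
    probit = function(eta) stats::pnorm(clip_eta(eta)),
    stop("unknown link: ", link, call. = FALSE)
  )
}

# Condition raised when a (bootstrap) sample cannot support the requested fit;
# redraw loops catch this class and resample.
degenerate_fit <- function(msg) {
  stop(structure(
    class = c("nnmicat_degenerate_fit", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_degenerate_error <- function(e) inherits(e, "nnmicat_degenerate_fit")

# Run `fn(attempt)` up to `max_redraws` times, retrying on degenerate-fit
# conditions only; any other error propagates immediately.
with_redraws <- function(fn, max_redraws = 100L) {
  for (attempt in seq_len(max_redraws)) {
    res <- tryCatch(fn(attempt), nnmicat_degenerate_fit = function(e) e)
    if (!is_degenerate_error(res)) return(res)
  }
  stop("degenerate fit persisted after ", max_redraws, " redraws: ",
       conditionMessage(res), call. = FALSE)
}

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Independent child seeds derived from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  set_seed_if_given(seed)
  sample.int(.Machine$integer.max, n)
}
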