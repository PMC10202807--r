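# Scale transforms shared by hierarchical priors and trend curves.
# Probabilities live on the logit scale, rates on the log scale,
# unbounded quantities on the identity scale.

.ms_scales <- c("logit", "log", "identity")

.check_scale <- function(scale) {
  if (!is.character(scale) || length(scale) != 1L || !scale %in% .ms_scales) {
    stop("`scale` must be one of ", paste(.ms_scales, collapse = ", "),
         call. = FALSE)
  }
  scale
}

# natural -> transformed
.fwd <- function(x, scale) {
  switch(scale,
    logit = stats::qlogis(x),
    log = log(x),
    identity = x
  )
}

# transformed -> natural
.inv <- function(x, scale) {
  switch(scale,
    logit = stats::plogis(x),
    log = exp(x),
    identity = x
  )
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
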