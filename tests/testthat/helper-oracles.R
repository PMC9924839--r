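# Independent oracles, written from the algorithm statements only --
# deliberately naive, element-by-element, and not sharing code with the
# package implementation.

# Exhaustive greedy R-peak oracle: walk every sample left to right;
# accept any strict local maximum above mpa that is at least miR samples
# after the previous acceptance.
oracle_preliminary_r <- function(x, mpa, miR) {
  out <- integer(0)
  last <- -Inf
  j <- 2L
  while (j <= length(x) - 1L) {
    if (x[j] > mpa && x[j - 1] < x[j] && x[j + 1] < x[j] &&
        (length(out) == 0 || j >= last + miR)) {
      out <- c(out, j)
      last <- j
    }
    j <- j + 1L
  }
  out
}

# One-way ANOVA F via R's linear-model machinery (independent route).
oracle_f_anova <- function(groups) {
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  anova(lm(values ~ g))[["F value"]][1]
}

# A feature vector with all 24 canonical amplitudes zero except those
# named in `...`.
fv <- function(...) {
  v <- setNames(numeric(24), lvh_features())
  args <- list(...)
  for (nm in names(args)) v[nm] <- args[[nm]]
  v
}

# Templates for the T-taller-than-R regime: no P wave, compact T so
# beats stay disjoint at ~110 bpm.
tachy_templates <- function(t_over_r) {
  default_lead_templates(t_over_r = t_over_r, p_amp = 0,
                         t_offset = 0.26, t_width = 0.045)
}
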