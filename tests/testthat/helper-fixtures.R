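# shared fixture builders (everything generated in code, nothing stored)

fixture_step_table <- function() {
  read_step_table(system.file("extdata", "stride_counts.csv",
                              package = "gaitwave"))
}

# a fast low-noise subject: 1 stride/s keeps the gait-locked component's
# fundamental well inside the delta passband
quick_subject <- function(duration = 30, stride_rate = 1, stride_cv = 0,
                          seed = 1, ...) {
  generate_subject(gait_model(stride_rate, stride_cv, duration = duration),
                   seed = seed, ...)
}

# fit amplitude of a sinusoid at frequency f in a signal's central span
# (regression on sin/cos isolates the component from edge transients)
sine_amplitude <- function(x, f, rate, trim = 0.2) {
  n <- length(x)
  idx <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  t <- (idx - 1) / rate
  co <- stats::lm.fit(cbind(sin(2 * pi * f * t), cos(2 * pi * f * t)),
                      x[idx])$coefficients
  sqrt(sum(co^2))
}

# naive textbook mixed-ANOVA sums of squares: explicit cell/subject means,
# no shortcuts shared with the package implementation
oracle_mixed_anova <- function(y, group) {
  # y: subjects x 2 matrix (one timepoint); group: "O"/"T" per subject
  n <- nrow(y)
  gl <- unique(group)
  grand <- mean(y)
  subj_mean <- rowMeans(y)
  cond_mean <- colMeans(y)
  group_mean <- sapply(gl, function(g) mean(y[group == g, ]))
  cell_mean <- sapply(1:2, function(c) sapply(gl, function(g)
    mean(y[group == g, c])))
  ng <- sapply(gl, function(g) sum(group == g))

  ss_group <- sum(2 * ng * (group_mean - grand)^2)
  ss_subj <- 2 * sum((subj_mean - group_mean[match(group, gl)])^2)
  ss_cond <- sum(n * (cond_mean - grand)^2)
  ss_int <- 0
  for (gi in seq_along(gl)) for (c in 1:2) {
    ss_int <- ss_int + ng[gi] * (cell_mean[gi, c] - group_mean[gi] -
                                   cond_mean[c] + grand)^2
  }
  ss_err <- 0
  for (j in 1:n) for (c in 1:2) {
    gi <- match(group[j], gl)
    ss_err <- ss_err + (y[j, c] - cell_mean[gi, c] - subj_mean[j] +
                          group_mean[gi])^2
  }
  df_err <- n - length(gl)
  list(F_group = unname((ss_group / (length(gl) - 1)) / (ss_subj / df_err)),
       F_condition = unname(ss_cond / (ss_err / df_err)),
       F_interaction = unname((ss_int / (length(gl) - 1)) /
                                (ss_err / df_err)))
}
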