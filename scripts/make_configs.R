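#!/usr/bin/env Rscript
# Regenerates the YAML experiment configs shipped under inst/configs.
# Full-scale configs mirror the package's simulation study layouts
# (tables 1-6: asymptotic calibration; 7-12: bootstrap vs asymptotic);
# the *s variants are scaled-down desk runs (reps = 1000, B = 200).

dir.create("inst/configs", recursive = TRUE, showWarnings = FALSE)

designs <- list(
  list(model = "example1",    theta = 0.3333),
  list(model = "example2",    theta = 0.24),
  list(model = "example3-hw", theta = 0.8))

paired <- function(d, method, reps, B) list(
  model = d$model, theta_true = d$theta, n = c(100L, 150L, 200L),
  reps = reps, lambda1 = c(-2, 1, 2), h1 = c(0.5, 1, 2),
  lambda2 = -2, h2 = c(0.5, 1, 2), pair_h = TRUE,
  method = method, B = B, alphas = c(0.05, 0.10), seed = 1L)

crossed <- function(d, method, reps, B) list(
  model = d$model, theta_true = d$theta, n = 200L,
  reps = reps, lambda1 = -2, h1 = c(0.5, 1, 2),
  lambda2 = -2, h2 = c(0.5, 1, 2), distinct_h = TRUE,
  method = method, B = B, alphas = c(0.05, 0.10), seed = 1L)

emit <- function(name, spec) {
  yaml::write_yaml(list(experiments = list(spec)),
                   file.path("inst/configs", paste0(name, ".yaml")))
}

for (i in seq_along(designs)) {
  d <- designs[[i]]
  emit(paste0("table", 2 * i - 1), paired(d, "asymptotic", 10000L, NULL))
  emit(paste0("table", 2 * i),     crossed(d, "asymptotic", 10000L, NULL))
  emit(paste0("table", 2 * i + 5), paired(d, "bootstrap", 10000L, 1000L))
  emit(paste0("table", 2 * i + 6), crossed(d, "bootstrap", 10000L, 1000L))
  emit(paste0("table", 2 * i + 5, "s"), paired(d, "bootstrap", 1000L, 200L))
  emit(paste0("table", 2 * i + 6, "s"), crossed(d, "bootstrap", 1000L, 200L))
}
cat("wrote", length(dir("inst/configs")), "configs\n")
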