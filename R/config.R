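#' Analysis configuration
#'
#' Collects the fixed analysis constants: the two PSTH resolutions (50-ms
#' bins normalized to a 1-s pre-CS baseline; 1-s bins normalized to a 20-s
#' pre-CS baseline — 20 baseline bins in both), the classification windows
#' (150 ms for short-latency responses, 10 s for persistent firing, 30 s of
#' CS for the modulation t-values), the 3-SD responsiveness threshold and
#' the two-tailed alpha.
#'
#' @param yaml_file optional YAML file whose top-level keys override the
#'   defaults below.
#' @param ... named overrides (applied after the YAML file).
#' @return list of class "cdfd_config".
#' @export
pipeline_config <- function(yaml_file = NULL, ...) {
  cfg <- list(
    bin_fast = 0.05,            # s; short-latency resolution
    window_fast = c(-1, 3),     # s relative to CS onset
    baseline_fast = c(-1, 0),   # 1-s baseline -> 20 bins
    bin_slow = 1,               # s; sustained resolution
    window_slow = c(-20, 30),
    baseline_slow = c(-20, 0),  # 20-s baseline -> 20 bins
    short_latency_window = c(0, 0.15),
    persistent_window = c(0, 10),
    persistent_min_bins = 2L,
    cs_window = c(0, 30),       # the thirty 1-s CS bins
    sd_threshold = 3,
    alpha = 0.05,
    # population used for the direction chi-square: "persistent" (the PFU
    # subset, as in the source analysis) or "analyzed" (all units with a
    # defined t-value)
    chisq_population = "persistent",
    # baseline used for the per-context profiles behind the modulation
    # contrast, window tests and population profiles: "common" (pooled
    # across both contexts' trials; baseline noise cancels in context
    # differences) or "per_context"
    context_baseline = "common",
    # baseline stats over the trial-averaged profile ("averaged", default)
    # or pooled across trials x baseline bins ("pooled")
    baseline_mode = "averaged",
    # classify on trials pooled across contexts ("pooled", default) or
    # within each context separately ("per_context")
    classify_contexts = "pooled")
  if (!is.null(yaml_file)) {
    ov <- yaml::read_yaml(yaml_file)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "cdfd_config")
}

validate_config <- function(cfg) {
  chk_div <- function(win, w, what) {
    if (abs(diff(win) / w - round(diff(win) / w)) > 1e-9)
      stop(what, " window is not a multiple of its bin width")
  }
  chk_div(cfg$window_fast, cfg$bin_fast, "fast")
  chk_div(cfg$baseline_fast, cfg$bin_fast, "fast baseline")
  chk_div(cfg$window_slow, cfg$bin_slow, "slow")
  chk_div(cfg$baseline_slow, cfg$bin_slow, "slow baseline")
  if (cfg$sd_threshold <= 0) stop("sd_threshold must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  invisible(cfg)
}
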