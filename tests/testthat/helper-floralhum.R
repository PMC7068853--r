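# Hand-built probe-log fragments with aligned timestamps, for exact checks.
toy_period <- function(rh_focal, rh_background = rep(50, length(rh_focal)),
                       timestamps = NULL, day = "d1", flower = "f1",
                       species = "toy", replicate = 1L, axis = "x",
                       offset_mm = 0) {
  if (is.null(timestamps))
    timestamps <- seq(31, 229, length.out = length(rh_focal))
  rbind(
    data.frame(day = day, flower = flower, species = species,
               replicate = replicate, axis = axis, offset_mm = offset_mm,
               probe_role = "focal", timestamp_s = timestamps,
               rh_pct = rh_focal, stringsAsFactors = FALSE),
    data.frame(day = day, flower = flower, species = species,
               replicate = replicate, axis = axis, offset_mm = offset_mm,
               probe_role = "background", timestamp_s = timestamps,
               rh_pct = rh_background, stringsAsFactors = FALSE)
  )
}

toy_log <- function(..., layout = transect_layout()) {
  cols <- c("day", "flower", "species", "replicate", "axis", "offset_mm",
            "probe_role", "timestamp_s", "rh_pct")
  parts <- lapply(list(...), function(d) as.data.frame(d)[, cols])
  floralhum:::validate_probe_log(do.call(rbind, parts), layout)
}

# A control-only log whose focal/background readings follow a known line.
toy_control_log <- function(focal, background, replicate = 1L, day = "d1") {
  toy_log(toy_period(focal, background, axis = "probe_control",
                     offset_mm = NA_real_, replicate = replicate, day = day))
}

# Minimal fitted-model stand-in for peak-calculation checks: peak formulas
# use only the spec and the named fixed effects.
fake_fit <- function(id, coefficients) {
  structure(list(spec = transect_model_spec(id),
                 coefficients = coefficients,
                 random_intercepts = numeric(0)),
            class = "transect_fit")
}

star_tree <- function(n, len = 1) {
  txt <- paste0("(", paste0("sp", seq_len(n), ":", len, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Brute-force peak search over a fine offset grid, the independent oracle
# for the closed-form vertex rules.
grid_peak <- function(I, A, B, range = c(-30, 30), by = 0.01) {
  xs <- seq(range[1], range[2], by = by)
  vals <- I + A * xs + B * xs^2
  list(x = xs[which.max(vals)], value = max(vals))
}
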