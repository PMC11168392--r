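# Internal helpers: RNG substreams, panel schema checks, grid checks.

# Deterministic 31-bit substream seed from a base seed plus arbitrary keys.
# Polynomial string hash mod (2^31 - 1); doubles stay < 2^53 so arithmetic
# is exact. Keys identify (trigger, readout, replicate, ...) so that adding
# replicates or readouts never perturbs the draws of existing ones.
substream_seed <- function(seed, ...) {
  keys <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(as.integer(seed) %% 2147483647)
  for (k in keys) {
    for (ch in utf8ToInt(k)) h <- (h * 131 + ch) %% 2147483647
    h <- (h * 131 + 7) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_substream <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

panel_cols <- c("trigger", "readout", "replicate", "time_h", "value")

# Validate the tidy time-series panel contract. `field` is optional
# (technical image fields); when present it joins the grouping key.
validate_panel <- function(panel, require_field = FALSE) {
  if (!is.data.frame(panel)) {
    stop("`panel` must be a data frame with columns ",
         paste(panel_cols, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(panel_cols, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (require_field && !"field" %in% names(panel)) {
    stop("panel is missing the `field` column (technical replicates)",
         call. = FALSE)
  }
  if (!is.numeric(panel$time_h) || !is.numeric(panel$value)) {
    stop("`time_h` and `value` must be numeric", call. = FALSE)
  }
  key <- c("trigger", "readout", "replicate",
           if ("field" %in% names(panel)) "field", "time_h")
  if (anyDuplicated(panel[key]) > 0) {
    stop("panel has duplicated (group, time_h) rows", call. = FALSE)
  }
  invisible(panel)
}

# Times must form a strictly increasing, uniform grid; returns dt.
check_uniform_grid <- function(time_h, tol = 1e-8) {
  if (length(time_h) < 2) stop("need at least 2 time points", call. = FALSE)
  dt <- diff(time_h)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > tol * max(dt)) {
    stop("time grid must be uniform", call. = FALSE)
  }
  mean(dt)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
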