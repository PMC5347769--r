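# Internal helpers: classed error conditions, seed plumbing, config merging.

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinscreen_config_error", "bilinscreen_error")))
}

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinscreen_input_error", "bilinscreen_error")))
}

calibration_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinscreen_calibration_error", "bilinscreen_error")))
}

degenerate_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinscreen_degenerate_error", "bilinscreen_error")))
}

io_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("bilinscreen_io_error", "bilinscreen_error")))
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x != as.integer(x) || x < min) {
    config_error(name, " must be a single integer >= ", min, " (got ", deparse(x), ")")
  }
  as.integer(x)
}

assert_proportion <- function(x, name, open_upper = FALSE) {
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (length(x) != 1 || !is.finite(x) || x < 0 || !hi_ok) {
    config_error(name, " must be a proportion in [0,", if (open_upper) "1)" else "1]",
                 " (got ", deparse(x), ")")
  }
  as.numeric(x)
}

assert_positive <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    config_error(name, " must be a single positive number (got ", deparse(x), ")")
  }
  as.numeric(x)
}

assert_seed <- function(seed) {
  if (length(seed) != 1 || !is.finite(seed) || seed < 0 || seed != as.integer(seed)) {
    config_error("seed must be a single non-negative integer")
  }
  as.integer(seed)
}

# Deterministic per-stage substreams derived from one run seed; kept < 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + 7L * as.integer(stage)
}

# Run `expr` under set.seed(seed), restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(assert_seed(seed))
  expr
}

# Recursive list merge: values in `override` replace those in `base`.
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CELL_CLASSES <- c("DP", "K5_only", "K8_only", "DN")
CONTROL_ROLES <- c("control_empty", "control_nonspecific", "control_gfp")
GATING_ROLES <- c("gating_mcf7", "gating_mcf10a")
ALL_ROLES <- c("treatment", CONTROL_ROLES, GATING_ROLES)
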