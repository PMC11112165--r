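# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# physical coordinate (um) of the centre of 1-based voxel index i along an axis
.vox_center <- function(i, voxel_size) (i - 0.5) * voxel_size

# longest run of TRUE in a logical vector (NAs count as FALSE)
.max_run <- function(x) {
  x[is.na(x)] <- FALSE
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    rlang::abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

.check_pos <- function(x, name, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(is.na(x)) || any(x <= 0)) {
    rlang::abort(sprintf("`%s` must be positive (length %d)", name, len))
  }
  invisible(x)
}

# deterministic per-stage seed derived from a global seed, kept < 2^31
.derive_seed <- function(seed, stage) {
  stage_codes <- vapply(utf8ToInt(stage), identity, numeric(1))
  as.integer((seed * 7919 + sum(stage_codes * seq_along(stage_codes))) %% 2147483647)
}
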