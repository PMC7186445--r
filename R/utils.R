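#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers never perturb each other.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' Pipeline stages draw their randomness from independent streams derived
#' from one global seed and the stage name, so reordering or re-running a
#' stage never silently reuses another stage's stream.
#'
#' @param global_seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double range
  h <- as.numeric(global_seed) %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# round-half-up for non-negative x (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# stratified k-fold assignment; returns integer fold id per row
stratified_folds <- function(labels, k) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
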