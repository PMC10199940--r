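# Shared constants and small helpers.

# Canonical 10-20 electrode order used throughout the package.
.EEG_CHANNELS <- c(
  "Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4", "Cz",
  "P3", "P4", "Pz", "T3", "T4", "T5", "T6", "O1", "O2"
)

.EEG_GROUPS <- c("A", "B", "C", "D")

# A, C: eyes open; B, D: eyes closed. C, D are the AD groups.
.GROUP_EYE <- c(A = "open", B = "closed", C = "open", D = "closed")
.GROUP_STATUS <- c(A = "healthy", B = "healthy", C = "ad", D = "ad")

.EEG_BANDS <- c("original", "beta", "alpha", "theta", "delta")

#' Canonical EEG channel names
#'
#' The 19 scalp electrodes of the international 10-20 placement system, in the
#' fixed order used by every function in this package.
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() .EEG_CHANNELS

#' Default quantile count for quantile graphs
#'
#' The rule of thumb `Q = round(2 * T^(1/3))` linking the number of quantile
#' bins to the series length; at `T = 1024` it gives `Q = 20`.
#'
#' @param n Series length.
#' @return Integer quantile count (at least 2).
#' @export
#' @examples
#' default_quantile_count(1024)
default_quantile_count <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  max(2L, as.integer(round(2 * n^(1 / 3))))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eeg <- function(...) stop(..., call. = FALSE)

check_group <- function(group) {
  if (!(is.character(group) && length(group) == 1 && group %in% .EEG_GROUPS)) {
    stop_eeg("`group` must be one of ", paste(.EEG_GROUPS, collapse = ", "))
  }
  group
}

check_band <- function(band) {
  if (!(is.character(band) && length(band) == 1 && band %in% .EEG_BANDS)) {
    stop_eeg(
      "unknown band '", paste(band, collapse = ","),
      "'; expected one of ", paste(.EEG_BANDS, collapse = ", ")
    )
  }
  band
}
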