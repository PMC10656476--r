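# Shared constants and small helpers.

# Single-year ages; 100 stands for the open interval "100+".
.AGES <- 0:100
.OPEN_AGE <- 100L
.AGE_LABELS <- c(as.character(0:99), "100+")
.FERT_AGES <- 15:49
.SEXES <- c("M", "F")
.REGIONS <- c("east", "middle_west")
.TIERS <- c("T1", "NT1", "T2", "T3")

abort_citypop <- function(message, class = "citypop_error", ...) {
  rlang::abort(message, class = unique(c(class, "citypop_error")), ...)
}

abort_validation <- function(message, ...) {
  abort_citypop(message, class = "citypop_validation_error", ...)
}

#' Convert between integer ages and serialized age labels
#'
#' Ages are single-year, 0 through 99, plus the open interval stored as the
#' integer 100 in memory and serialized as the literal string `"100+"`.
#'
#' @param x Integer ages 0..100, or character labels `"0"`..`"99"`, `"100+"`.
#' @return `age_to_int()` returns an integer vector; `age_to_label()` a
#'   character vector.
#' @examples
#' age_to_int(c("3", "100+"))
#' age_to_label(c(0L, 100L))
#' @export
age_to_int <- function(x) {
  if (is.numeric(x)) {
    a <- as.integer(x)
  } else {
    x <- as.character(x)
    x[x == "100+"] <- "100"
    a <- suppressWarnings(as.integer(x))
  }
  if (anyNA(a) || any(a < 0L | a > .OPEN_AGE)) {
    abort_validation("ages must be 0..99 or '100+'")
  }
  a
}

#' @rdname age_to_int
#' @export
age_to_label <- function(x) {
  a <- age_to_int(x)
  ifelse(a == .OPEN_AGE, "100+", as.character(a))
}

.check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort_validation(sprintf("`%s` must be a single finite number in [%s, %s]",
                             name, format(min), format(max)))
  }
  as.numeric(x)
}

.check_flag_in <- function(x, name, choices) {
  if (length(x) != 1L || !x %in% choices) {
    abort_validation(sprintf("`%s` must be one of: %s", name,
                             paste(choices, collapse = ", ")))
  }
  x
}

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer regardless of the user-supplied master seed.
.substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
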