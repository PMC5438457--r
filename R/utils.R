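`%||%` <- function(a, b) if (is.null(a)) b else a

#' Largest-remainder integer allocation
#'
#' Apportions `total` integer units across cells proportionally to `props`,
#' using the largest-remainder (Hamilton) rule: each cell receives the floor
#' of its exact share, and the leftover units go to the cells with the
#' largest fractional parts (ties broken by position).
#'
#' @param props Non-negative numeric vector of proportions or raw sizes
#'   (they are normalised internally).
#' @param total Non-negative integer total to allocate.
#' @return Integer vector summing exactly to `total`.
#' @examples
#' largest_remainder(c(1, 1, 1) / 3, 100) # 34 33 33
#' @export
largest_remainder <- function(props, total) {
  stopifnot(is.numeric(props), length(props) >= 1, all(props >= 0),
            length(total) == 1, total >= 0)
  total <- as.integer(round(total))
  if (total == 0L) return(integer(length(props)))
  s <- sum(props)
  if (s <= 0) stop("proportions must have a positive sum")
  exact <- props / s * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- exact - base
    idx <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Derive a named substream seed from a master seed
#'
#' Each simulation module (population, frame, dialer) consumes its own seed
#' derived deterministically from the master seed and a stream label, so that
#' toggling one module never perturbs another's draws.
#'
#' @param master Integer master seed.
#' @param stream Character stream label, e.g. `"population"`.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stream))
  u <- utf8ToInt(stream)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(master)) * 48271 + h * 16807) %% 2147483647)
}

# Paste the dimension-level columns of `df` into a single "F|18-29|urban" key.
stratum_key <- function(df, dim_names) {
  do.call(paste, c(lapply(dim_names, function(d) as.character(df[[d]])),
                   list(sep = "|")))
}

# Split keys back into a data.frame of dimension levels.
split_stratum_key <- function(keys, dim_names) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- dim_names
  out
}
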