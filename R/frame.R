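#' Number registry guaranteeing cross-batch uniqueness
#'
#' Random digit dialling may need several pools over a run; numbers must
#' never be re-created across batches. The registry records every suffix
#' ever generated per prefix and is consulted (and updated) by
#' [build_number_pool()].
#'
#' @return An environment-backed registry object.
#' @export
new_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$used <- list()    # prefix -> integer vector of used suffixes (1-based)
  e$batches <- 0L
  class(e) <- "mps_registry"
  e
}

#' @rdname new_registry
#' @param registry A registry created by [new_registry()].
#' @export
registry_size <- function(registry) {
  sum(vapply(registry$used, length, 1L))
}

# Draw k suffixes from 1..space not already used under `prefix`.
draw_suffixes <- function(registry, prefix, space, k) {
  used <- registry$used[[prefix]] %||% integer(0)
  if (space - length(used) < k)
    stop("number space exhausted for prefix ", prefix)
  got <- integer(0)
  while (length(got) < k) {
    cand <- sample.int(space, min(space, ceiling((k - length(got)) * 1.25) + 8L))
    cand <- setdiff(cand, c(used, got))
    got <- c(got, cand[seq_len(min(length(cand), k - length(got)))])
  }
  registry$used[[prefix]] <- c(used, got)
  got
}

#' Generate a pool of unique random phone numbers
#'
#' Computer-generates `pool_size` unique candidate numbers under the
#' declared MNO prefixes, allocating the pool across operators exactly
#' proportionally to market share (largest-remainder rounding), so the frame
#' reflects the subscriber market. Uniqueness is enforced across every batch
#' drawn through the same registry.
#'
#' @param plans An [mno_plan()] data.frame.
#' @param pool_size Number of candidate numbers to generate.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers embedding pool generation in a larger seeded run keep
#'   a single stream).
#' @param registry A [new_registry()]; created fresh if `NULL`.
#' @return A `data.frame` with columns `number`, `prefix`, `batch`, carrying
#'   the registry as attribute `"registry"`.
#' @examples
#' pool <- build_number_pool(mno_plan(c("017", "019"), c(0.6, 0.4)), 100, seed = 1)
#' table(pool$prefix)
#' @export
build_number_pool <- function(plans, pool_size, seed = NULL, registry = NULL) {
  plans <- mno_plan(plans$prefix, plans$share, plans$suffix_length)
  pool_size <- as.integer(pool_size)
  stopifnot(pool_size >= 0)
  if (!is.null(seed)) set.seed(derive_seed(seed, "frame"))
  if (is.null(registry)) registry <- new_registry()
  space <- 10^plans$suffix_length
  used0 <- vapply(plans$prefix, function(p)
    length(registry$used[[p]] %||% integer(0)), 1L)
  if (pool_size > sum(space - used0))
    stop("pool_size exceeds the remaining number space")
  alloc <- largest_remainder(plans$share, pool_size)
  # shares pointing at exhausted prefixes would starve: check per prefix
  if (any(alloc > space - used0))
    stop("pool_size exceeds the number space of prefix ",
         plans$prefix[which(alloc > space - used0)[1]])
  registry$batches <- registry$batches + 1L
  rows <- lapply(seq_len(nrow(plans)), function(i) {
    if (alloc[i] == 0L) return(NULL)
    sfx <- draw_suffixes(registry, plans$prefix[i], space[i], alloc[i])
    data.frame(
      number = paste0(plans$prefix[i],
                      formatC(sfx - 1L, width = plans$suffix_length[i],
                              format = "d", flag = "0")),
      prefix = plans$prefix[i], batch = registry$batches,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(number = character(0),
                                      prefix = character(0),
                                      batch = integer(0))
  rownames(out) <- NULL
  attr(out, "registry") <- registry
  out
}

#' Attach working status and owners to a number pool
#'
#' Marks a fraction `Y` of the pool as nonworking and links each working
#' number to a handset: every person contributes `T_i` phone slots, and each
#' working number reaches a slot chosen uniformly at random. This makes a
#' person's chance of being rung exactly proportional to the number of
#' phones they own. Under the default `"exact"` assignment the pool contains
#' exactly `round(pool_size * (1 - Y))` working numbers (the operator's
#' subscription census fixes the working share of any large pool);
#' `"bernoulli"` draws each number's status independently. For small
#' replacement batches, `"exact"` uses stochastic rounding so the expected
#' working fraction stays `1 - Y`.
#'
#' @param pool A pool from [build_number_pool()].
#' @param population An `mps_population`.
#' @param Y True nonworking fraction in `[0, 1)`.
#' @param seed Optional seed (`NULL` = current stream).
#' @param method `"exact"` or `"bernoulli"`.
#' @return The pool with logical `working` and integer `owner_id` columns
#'   (`NA` for nonworking numbers).
#' @export
assign_numbers <- function(pool, population, Y, seed = NULL,
                           method = c("exact", "bernoulli")) {
  method <- match.arg(method)
  stopifnot(inherits(population, "mps_population"), Y >= 0, Y < 1)
  if (!is.null(seed)) set.seed(derive_seed(seed, "frame-assign"))
  n <- nrow(pool)
  working <- logical(n)
  if (n > 0) {
    if (method == "bernoulli") {
      working <- stats::runif(n) < (1 - Y)
    } else {
      exact <- n * (1 - Y)
      k <- floor(exact) + (stats::runif(1) < (exact - floor(exact)))
      working[sample.int(n, k)] <- TRUE
    }
  }
  p <- population$persons
  slots <- rep(p$id, p$n_phones)
  if (length(slots) == 0 && any(working))
    stop("population owns no phones; no working number can be assigned")
  owner <- rep(NA_integer_, n)
  owner[working] <- slots[sample.int(length(slots), sum(working),
                                     replace = TRUE)]
  pool$working <- working
  pool$owner_id <- owner
  pool
}

#' Estimate the nonworking-number fraction Y from a test pool
#'
#' Before the main survey, a smaller test pool is dialled to estimate the
#' proportion Y of generated numbers that are nonworking. Only resolved
#' outcomes enter the estimate; unresolved numbers (no answer within the
#' redial budget at estimation time) are left to the dialer's own
#' reclassification rule.
#'
#' @param statuses Character vector of call statuses, containing
#'   `"verified_nonworking"`, `"verified_household"` and possibly
#'   `"unresolved"`.
#' @return A list of class `mps_Y`: `Y_hat`, binomial `se`, `n_resolved`.
#' @examples
#' estimate_nonworking_fraction(rep(c("verified_nonworking",
#'                                    "verified_household"), c(25, 175)))
#' @export
estimate_nonworking_fraction <- function(statuses) {
  ok <- c("verified_nonworking", "verified_household", "unresolved")
  if (!all(statuses %in% ok))
    stop("unknown call status: ",
         paste(unique(setdiff(statuses, ok)), collapse = ", "))
  resolved <- statuses[statuses != "unresolved"]
  m <- length(resolved)
  if (m == 0) stop("no resolved outcomes; cannot estimate Y")
  y <- mean(resolved == "verified_nonworking")
  structure(list(Y_hat = y, se = sqrt(y * (1 - y) / m), n_resolved = m),
            class = "mps_Y")
}

#' @export
print.mps_Y <- function(x, ...) {
  cat(sprintf("Nonworking fraction Y = %.4f (SE %.4f, %d resolved numbers)\n",
              x$Y_hat, x$se, x$n_resolved))
  invisible(x)
}

#' Inflate a target sample size for nonworking numbers
#'
#' With a fraction Y of generated numbers nonworking, obtaining `target_n`
#' working contacts requires dialling `ceiling(target_n / (1 - Y))`
#' numbers.
#'
#' @param target_n Required number of working contacts.
#' @param Y Nonworking fraction in `[0, 1)`.
#' @return Integer inflated count.
#' @examples
#' inflate_sample_size(1000, 0.2) # 1250
#' @export
inflate_sample_size <- function(target_n, Y) {
  stopifnot(length(target_n) == 1, target_n >= 0, length(Y) == 1)
  if (Y >= 1 || Y < 0) stop("Y must be in [0, 1): no working numbers exist at Y = 1")
  # guard the ceiling against floating noise in 1 / (1 - Y)
  as.integer(ceiling(round(target_n / (1 - Y), 9)))
}
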