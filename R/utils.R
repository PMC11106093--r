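# Shared helpers: canonical dyad keys, interval arithmetic, input checks.

#' Canonical pair key for an unordered dyad
#'
#' Dyads are unordered; a pair is always stored under the lexicographically
#' sorted id tuple so that `(A, B)` and `(B, A)` map to the same key.
#'
#' @param id_a,id_b Character vectors of individual ids (recycled pairwise).
#' @param sep Separator placed between the two ids.
#' @return Character vector of canonical keys.
#' @examples
#' pair_key("f12", "f03")  # "f03|f12"
#' @export
pair_key <- function(id_a, id_b, sep = "|") {
  stopifnot(length(id_a) == length(id_b))
  if (any(id_a == id_b)) {
    stop("a pair must consist of two distinct individuals: ",
         paste(unique(id_a[id_a == id_b]), collapse = ", "))
  }
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = sep)
}

#' Split canonical pair keys back into the two member ids
#'
#' @param key Character vector of keys produced by [pair_key()].
#' @param sep Separator used when the key was built.
#' @return A two-column character matrix (`id_a` sorts before `id_b`).
#' @export
pair_members <- function(key, sep = "|") {
  parts <- strsplit(key, sep, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed pair key: ", paste(key[bad], collapse = ", "))
  out <- matrix(unlist(parts), ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("id_a", "id_b")))
  out
}

#' Total length of a union of intervals
#'
#' Computes the Lebesgue measure of the union of closed intervals
#' `[start_i, end_i]`. Overlapping and duplicated intervals are merged, so
#' concurrent behavioural states never double-count.
#'
#' @param starts,ends Numeric vectors of interval endpoints, `ends >= starts`.
#' @return A single non-negative number.
#' @examples
#' interval_union_length(c(0, 100), c(300, 400))  # 400, not 600
#' @export
interval_union_length <- function(starts, ends) {
  m <- merge_intervals(starts, ends)
  if (nrow(m) == 0L) return(0)
  sum(m[, 2L] - m[, 1L])
}

# Merge intervals into disjoint sorted form; returns a 2-column matrix.
merge_intervals <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  keep <- !(is.na(starts) | is.na(ends))
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(matrix(numeric(0), ncol = 2L))
  if (any(ends < starts)) stop("interval with end < start")
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

# Subtract a union of intervals (bs, be) from a union (as, ae); returns the
# remaining measure. Used to drop out-of-sight time from state unions.
interval_union_minus <- function(as, ae, bs, be) {
  a <- merge_intervals(as, ae)
  b <- merge_intervals(bs, be)
  if (nrow(a) == 0L) return(0)
  if (nrow(b) == 0L) return(sum(a[, 2L] - a[, 1L]))
  total <- 0
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1L]; e <- a[i, 2L]
    cut <- b[b[, 2L] > s & b[, 1L] < e, , drop = FALSE]
    covered <- if (nrow(cut) == 0L) 0 else
      sum(pmin(cut[, 2L], e) - pmax(cut[, 1L], s))
    total <- total + (e - s) - covered
  }
  total
}

# stop() with a located row context, used by the readers.
row_error <- function(file, line, msg) {
  stop(sprintf("%s, line %d: %s", file, line, msg), call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
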