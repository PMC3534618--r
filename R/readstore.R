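# In-memory map from canonical packed sequence to observation counts.
#
# Buckets are keyed by MurmurHash2 of the payload bytes only (never the
# header fields, to keep the hash well mixed over actual sequence content);
# collisions inside a bucket are resolved by full packed comparison, so the
# hash choice affects speed, never correctness. Entries are environments so
# they can be promoted between the optional singleton set and the map
# without copying.

#' Create an empty read store
#'
#' @param singleton_set if `TRUE`, the first observation of every key is
#'   held in a membership-only set and promoted to the counting map on its
#'   second observation. Externally indistinguishable from the default
#'   map-only mode; internally it keeps the counting map restricted to
#'   genuinely redundant sequences.
#' @return an opaque store object.
#' @export
read_store <- function(singleton_set = FALSE) {
  store <- new.env(parent = emptyenv())
  store$buckets <- new.env(hash = TRUE, parent = emptyenv())
  store$set_buckets <- new.env(hash = TRUE, parent = emptyenv())
  store$ids <- new.env(hash = TRUE, parent = emptyenv())
  store$singleton <- isTRUE(singleton_set)
  store$n_entries <- 0
  store$n_obs <- 0
  store$next_id <- 0L
  class(store) <- "read_store"
  store
}

#' Hash the payload of a packed sequence
#'
#' 32-bit MurmurHash2 with seed 0, computed over the payload bytes only;
#' deterministic across runs and platforms.
#'
#' @param p a `packed_seq`.
#' @return the hash as a double holding an unsigned 32-bit value.
#' @export
hash_key <- function(p) {
  .murmur2_cpp(p$payload, 0)
}

MAX_COUNT <- 2^53  # doubles hold exact integers up to here

new_entry <- function(store, key, orientation, name, quality, quality2,
                      len1) {
  e <- new.env(parent = emptyenv())
  e$packed <- key
  e$key_id <- paste0("u", store$next_id)
  store$next_id <- store$next_id + 1L
  fwd <- orientation %in% c("forward", "original")
  e$fwd <- if (fwd) 1 else 0
  e$rev <- if (fwd) 0 else 1
  e$first_orientation <- orientation
  e$first_name <- name
  e$first_quality <- quality
  e$first_quality2 <- quality2
  e$len1 <- len1
  assign(e$key_id, e, envir = store$ids)
  e
}

bucket_find <- function(buckets, h, key) {
  lst <- if (exists(h, envir = buckets, inherits = FALSE))
    get(h, envir = buckets) else NULL
  for (e in lst) if (packed_equal(e$packed, key)) return(e)
  NULL
}

bucket_add <- function(buckets, h, e) {
  lst <- if (exists(h, envir = buckets, inherits = FALSE))
    get(h, envir = buckets) else list()
  assign(h, c(lst, list(e)), envir = buckets)
}

bucket_remove <- function(buckets, h, e) {
  lst <- get(h, envir = buckets)
  keep <- !vapply(lst, identical, logical(1), e)
  assign(h, lst[keep], envir = buckets)
}

increment <- function(e, orientation) {
  if (e$fwd + e$rev >= MAX_COUNT)
    stop("count overflow for key ", e$key_id, call. = FALSE)
  if (orientation %in% c("forward", "original")) e$fwd <- e$fwd + 1
  else e$rev <- e$rev + 1
}

# core observation; returns list(entry, is_new). `h` may be precomputed.
observe_entry <- function(store, key, orientation, name, quality = NULL,
                          quality2 = NULL, len1 = NULL, h = NULL) {
  h <- h %||% as.character(hash_key(key))
  store$n_obs <- store$n_obs + 1
  e <- bucket_find(store$buckets, h, key)
  if (!is.null(e)) {
    increment(e, orientation)
    return(list(entry = e, is_new = FALSE))
  }
  if (store$singleton) {
    e <- bucket_find(store$set_buckets, h, key)
    if (!is.null(e)) {
      # second observation: promote from the set to the counting map
      bucket_remove(store$set_buckets, h, e)
      bucket_add(store$buckets, h, e)
      increment(e, orientation)
      return(list(entry = e, is_new = FALSE))
    }
    e <- new_entry(store, key, orientation, name, quality, quality2, len1)
    bucket_add(store$set_buckets, h, e)
  } else {
    e <- new_entry(store, key, orientation, name, quality, quality2, len1)
    bucket_add(store$buckets, h, e)
  }
  store$n_entries <- store$n_entries + 1
  list(entry = e, is_new = TRUE)
}

#' Record one observation of a canonical key
#'
#' @param store a [read_store()].
#' @param key a canonical `packed_seq` (from [canonical_single()] /
#'   [canonical_pair()] followed by [pack()]).
#' @param orientation `"forward"`/`"reverse"` (single-end) or
#'   `"original"`/`"swapped"` (pairs): which form the input read had.
#' @param name the read name; retained only for the first observation.
#' @param quality,quality2 optional qualities retained for the first
#'   observation when name/quality restoration is enabled.
#' @param len1 for concatenated pair keys, the base length of mate 1 so the
#'   pair can be split exactly.
#' @return `TRUE` when this key was never seen before, else `FALSE`.
#' @export
observe <- function(store, key, orientation, name, quality = NULL,
                    quality2 = NULL, len1 = NULL) {
  stopifnot(inherits(store, "read_store"), inherits(key, "packed_seq"))
  observe_entry(store, key, orientation, name, quality, quality2,
                len1)$is_new
}

entry_as_list <- function(e) {
  list(key_id = e$key_id, forward_count = e$fwd, reverse_count = e$rev,
       first_name = e$first_name, first_quality = e$first_quality,
       first_quality2 = e$first_quality2,
       first_orientation = e$first_orientation, len1 = e$len1,
       packed = e$packed)
}

#' Look up the count entry for a key
#'
#' @inheritParams observe
#' @return a list with `forward_count`, `reverse_count`, `first_name`,
#'   `key_id` (and pair metadata), or `NULL` if the key was never observed.
#' @export
lookup <- function(store, key) {
  h <- as.character(hash_key(key))
  e <- bucket_find(store$buckets, h, key)
  if (is.null(e) && store$singleton)
    e <- bucket_find(store$set_buckets, h, key)
  if (is.null(e)) return(NULL)
  entry_as_list(e)
}

get_entry_by_id <- function(store, key_id) {
  if (!exists(key_id, envir = store$ids, inherits = FALSE)) return(NULL)
  get(key_id, envir = store$ids)
}

#' Switch a store to singleton-set mode
#'
#' Must be called before any observation.
#' @inheritParams observe
#' @export
enable_singleton_set <- function(store) {
  if (store$n_obs > 0)
    stop("singleton-set mode must be enabled before any observation",
         call. = FALSE)
  store$singleton <- TRUE
  invisible(store)
}

#' Extract all entries of a store
#'
#' Entries are returned in first-observation order (key ids are assigned
#' sequentially).
#' @inheritParams observe
#' @return a list of entry lists as returned by [lookup()].
#' @export
store_entries <- function(store) {
  if (store$next_id == 0L) return(list())
  ids <- paste0("u", seq_len(store$next_id) - 1L)
  lapply(ids, function(id) entry_as_list(get(id, envir = store$ids)))
}

#' @export
print.read_store <- function(x, ...) {
  cat(sprintf("<read_store: %d entries, %d observations%s>\n",
              x$n_entries, x$n_obs,
              if (x$singleton) ", singleton set" else ""))
  invisible(x)
}
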