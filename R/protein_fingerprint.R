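## Hashed 3D residue-neighborhood fingerprints.
##
## For every atom of a structure, the neighborhood is the set of residues
## having at least one atom within `radius` of that atom (the central
## atom's own residue is always a member, at distance zero; the cutoff is
## inclusive). Duplicate member-sets across atoms are removed, each
## surviving set's one-letter codes are sorted into a pattern key (a
## multiset: duplicated codes are kept), and each key is hashed to one bit
## of a fixed-length binary array. Hash collisions are tolerated by design
## and made rarer by the prime array length.

# Canonical position-annotated member string, e.g. "F24:G25:R27". Dedup of
# neighborhoods operates on these, i.e. before letter-sorting.
canonical_members <- function(codes, numbers) {
  o <- order(numbers)
  paste(paste0(codes[o], numbers[o]), collapse = ":")
}

members_from_canonical <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  data.frame(residue_code = sub("^([A-Z]).*$", "\\1", parts),
             residue_number = as.integer(sub("^[A-Z]", "", parts)),
             stringsAsFactors = FALSE)
}

#' Residue neighborhood of one atom
#'
#' All residues of the structure having at least one atom with Euclidean
#' distance `<= radius` from the given atom. The atom's own residue is
#' always included.
#'
#' @param structure A `ProteinStructure`.
#' @param atom_index Row index of the central atom in `structure$atoms`.
#' @param radius Neighborhood radius in Angstrom (> 0).
#' @return data.frame with columns `residue_code`, `residue_number`,
#'   ordered by residue number.
#' @export
atom_neighborhood <- function(structure, atom_index, radius = 5.0) {
  stopifnot(inherits(structure, "ProteinStructure"), radius > 0)
  a <- structure$atoms
  if (!(atom_index %in% seq_len(nrow(a))))
    stop("atom_index is not an atom of the structure")
  d2 <- (a$x - a$x[atom_index])^2 + (a$y - a$y[atom_index])^2 +
    (a$z - a$z[atom_index])^2
  inr <- d2 <= radius^2
  members_from_canonical(
    canonical_members_unique(a$residue_code[inr], a$residue_number[inr]))
}

canonical_members_unique <- function(codes, numbers) {
  first <- !duplicated(numbers)
  canonical_members(codes[first], numbers[first])
}

# Cell-list (uniform grid) neighbor search: atoms are binned into cubic
# cells of side `radius`; candidates for an atom are the atoms of its 27
# surrounding cells. Exact: candidates are then distance-filtered, so the
# result equals the brute-force all-pairs scan.
patterns_grid <- function(a, radius) {
  n <- nrow(a)
  cx <- floor(a$x / radius); cy <- floor(a$y / radius); cz <- floor(a$z / radius)
  key <- paste(cx, cy, cz, sep = ",")
  cells <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  r2 <- radius^2
  out <- character(n)
  for (i in seq_len(n)) {
    nbr_keys <- paste(cx[i] + offs[, 1], cy[i] + offs[, 2], cz[i] + offs[, 3],
                      sep = ",")
    cand <- unlist(cells[nbr_keys], use.names = FALSE)
    d2 <- (a$x[cand] - a$x[i])^2 + (a$y[cand] - a$y[i])^2 +
      (a$z[cand] - a$z[i])^2
    hit <- cand[d2 <= r2]
    out[i] <- canonical_members_unique(a$residue_code[hit],
                                       a$residue_number[hit])
  }
  out
}

patterns_brute <- function(a, radius) {
  n <- nrow(a)
  d <- as.matrix(stats::dist(as.matrix(a[, c("x", "y", "z")])))
  r <- radius
  vapply(seq_len(n), function(i) {
    hit <- which(d[i, ] <= r)
    canonical_members_unique(a$residue_code[hit], a$residue_number[hit])
  }, character(1))
}

#' Unique residue-neighborhood patterns of a structure
#'
#' Sweeps every atom as a neighborhood center and removes duplicate
#' member-sets (atoms frequently share exactly the same neighbor set).
#' Deduplication operates on position-annotated member-sets, before
#' letter-sorting. The result is independent of atom order.
#'
#' @inheritParams atom_neighborhood
#' @param method `"grid"` (cell-list spatial index, default) or `"brute"`
#'   (all-pairs distance scan, kept as the exactness oracle). Both return
#'   identical sets.
#' @return Sorted character vector of canonical member strings: each
#'   member is `code` followed by residue number, members joined by `":"`
#'   in residue-number order, e.g. `"R23:F24:G25:F27"`.
#' @export
unique_patterns <- function(structure, radius = 5.0,
                            method = c("grid", "brute")) {
  stopifnot(inherits(structure, "ProteinStructure"), radius > 0)
  method <- match.arg(method)
  a <- structure$atoms
  per_atom <- switch(method,
                     grid = patterns_grid(a, radius),
                     brute = patterns_brute(a, radius))
  sort(unique(per_atom))
}

#' Encode a neighborhood pattern as a sorted-letter key
#'
#' One-letter codes are extracted with multiplicity (two phenylalanines at
#' different positions both contribute an F), sorted lexicographically and
#' concatenated: the neighborhood \{R27, F24, G25, F27\} encodes as
#' `"FFGR"`.
#'
#' @param pattern A canonical member string from [unique_patterns()], or a
#'   data.frame with columns `residue_code`, `residue_number`.
#' @return Single string: the pattern key.
#' @export
encode_pattern <- function(pattern) {
  if (is.data.frame(pattern)) {
    codes <- pattern$residue_code
  } else {
    stopifnot(is.character(pattern), length(pattern) == 1)
    if (!nzchar(pattern)) stop("empty pattern")
    codes <- members_from_canonical(pattern)$residue_code
  }
  if (length(codes) == 0) stop("empty pattern")
  paste(sort(codes), collapse = "")
}

#' Hash a pattern key to a bit index
#'
#' Deterministic, platform- and run-stable: a 32-bit FNV-1a digest of the
#' ASCII key reduced modulo `n_bits`. Distinct keys may collide; collisions
#' are tolerated by design.
#'
#' @param key Pattern key string(s) from [encode_pattern()]. Vectorized.
#' @param n_bits Length of the fingerprint array (>= 2).
#' @return Integer bit index (or vector of them) in `[0, n_bits)`.
#' @export
hash_key <- function(key, n_bits = default_nbits()) {
  stopifnot(is.character(key), n_bits >= 2)
  if (any(!nzchar(key))) stop("empty key")
  vapply(key, function(k) as.integer(fnv1a32(k) %% n_bits), integer(1),
         USE.NAMES = FALSE)
}

#' Protein structural fingerprint
#'
#' The binary fingerprint of a structure: one bit per hashed
#' sorted-residue-key of its unique atom neighborhoods. Invariant under
#' rigid rotation and translation and under atom record order.
#'
#' @inheritParams unique_patterns
#' @param n_bits Fingerprint length; defaults to 16,381, the largest prime
#'   below 2^14.
#' @return Object of class `ProteinFingerprint`: list with `structure_id`,
#'   `n_bits`, `radius`, sorted `on_bits` (0-based indices), and `keys`
#'   (sorted unique pattern keys, pre-hash).
#' @export
fingerprint <- function(structure, radius = 5.0, n_bits = default_nbits(),
                        method = c("grid", "brute")) {
  pats <- unique_patterns(structure, radius = radius, method = method)
  keys <- sort(unique(vapply(pats, encode_pattern, character(1),
                             USE.NAMES = FALSE)))
  bits <- sort(unique(hash_key(keys, n_bits)))
  structure(
    list(structure_id = structure$structure_id, n_bits = as.integer(n_bits),
         radius = radius, on_bits = bits, keys = keys,
         n_patterns = length(pats)),
    class = "ProteinFingerprint")
}

#' @export
print.ProteinFingerprint <- function(x, ...) {
  cat(sprintf("ProteinFingerprint %s: %d/%d bits on (r = %g A, %d patterns)\n",
              x$structure_id, length(x$on_bits), x$n_bits, x$radius,
              x$n_patterns))
  invisible(x)
}

#' Jaccard similarity of two protein fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bit sets. With `use = "keys"`
#' the comparison runs on pre-hash pattern keys instead, which is immune to
#' hash collisions.
#'
#' @param a,b `ProteinFingerprint` objects with equal `n_bits`.
#' @param use `"bits"` (default, post-hash) or `"keys"` (pre-hash).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b, use = c("bits", "keys")) {
  use <- match.arg(use)
  stopifnot(inherits(a, "ProteinFingerprint"),
            inherits(b, "ProteinFingerprint"))
  if (use == "bits") {
    if (a$n_bits != b$n_bits) stop("fingerprints have different n_bits")
    sa <- a$on_bits; sb <- b$on_bits
  } else {
    sa <- a$keys; sb <- b$keys
  }
  if (length(sa) == 0 && length(sb) == 0)
    stop("Jaccard undefined: both fingerprints empty")
  length(intersect(sa, sb)) / length(union(sa, sb))
}

#' Pairwise Jaccard similarity matrix
#'
#' @param fps List of `ProteinFingerprint` objects with uniform `n_bits`.
#' @param use Passed to [jaccard()].
#' @return Symmetric matrix with unit diagonal, dimnames = structure ids.
#' @export
similarity_matrix <- function(fps, use = c("bits", "keys")) {
  use <- match.arg(use)
  stopifnot(length(fps) >= 2)
  nb <- vapply(fps, function(f) f$n_bits, integer(1))
  if (length(unique(nb)) != 1) stop("fingerprints have different n_bits")
  ids <- vapply(fps, function(f) f$structure_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate structure ids")
  n <- length(fps)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- jaccard(fps[[i]], fps[[j]], use = use)
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Closest structure pairs by similarity
#'
#' All unordered pairs ranked by descending similarity (ties broken by
#' target id for determinism).
#'
#' @param sim Symmetric similarity matrix with dimnames.
#' @param n_pairs Number of top pairs to report; default all.
#' @return data.frame with `target`, `partner`, `similarity`.
#' @export
closest_pairs <- function(sim, n_pairs = NULL) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim), nrow(sim) >= 2)
  ids <- rownames(sim)
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  out <- data.frame(target = ids[idx[, 1]], partner = ids[idx[, 2]],
                    similarity = sim[idx], stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$target, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(n_pairs)) out <- utils::head(out, n_pairs)
  out
}

#' Write a fingerprint to a plain-text file
#'
#' Format: a header line `id <TAB> n_bits <TAB> radius`, then one on-bit
#' index per line.
#'
#' @param fp A `ProteinFingerprint` (or ligand fingerprint with the same
#'   fields).
#' @param path Output file path.
#' @export
write_fingerprint <- function(fp, path) {
  header <- paste(fp$structure_id, fp$n_bits, fp$radius %||% NA, sep = "\t")
  writeLines(c(header, as.character(fp$on_bits)), path)
  invisible(path)
}

#' Read a fingerprint written by [write_fingerprint()]
#' @param path File path.
#' @return A `ProteinFingerprint`.
#' @export
read_fingerprint <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  bits <- as.integer(lines[-1])
  structure(
    list(structure_id = hdr[1], n_bits = as.integer(hdr[2]),
         radius = suppressWarnings(as.numeric(hdr[3])),
         on_bits = sort(unique(bits)), keys = NULL,
         n_patterns = NA_integer_),
    class = "ProteinFingerprint")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
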