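## Ligand circular fingerprints (ECFP6).
##
## Molecules are encoded as folded binary Morgan fingerprints of bond
## radius 3 over 2048 bits. The fingerprint itself is computed by RDKit (an
## established ECFP implementation), driven through the `python`
## interpreter with a small bundled script; this module supplies the
## tabular interface, error reporting and the binary matrix assembly.

find_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no `python` interpreter on PATH (required for ECFP6 fingerprints)")
  py
}

#' ECFP6 fingerprints for a table of SMILES
#'
#' Standard folded binary Morgan circular fingerprints with bond radius 3
#' and 2048 bits (ECFP6). Deterministic; canonicalization-invariant (two
#' SMILES spellings of one molecule give identical fingerprints). SMILES
#' are used as given (no salt stripping); multi-fragment inputs are
#' reported in the `note` column.
#'
#' @param molecules data.frame with columns `molecule_id` and `smiles`.
#' @param n_bits Folded length, default 2048.
#' @param radius Bond radius, default 3.
#' @return List with `fps`: binary matrix (`molecule_id` rows x `n_bits`
#'   columns), and `report`: per-molecule data.frame (`molecule_id`,
#'   `status`, `note`).
#' @export
ecfp6 <- function(molecules, n_bits = 2048L, radius = 3L) {
  stopifnot(is.data.frame(molecules),
            all(c("molecule_id", "smiles") %in% names(molecules)))
  if (anyDuplicated(molecules$molecule_id))
    stop("duplicate molecule_id values")
  py <- find_python()
  script <- system.file("python", "ecfp6_bits.py", package = "proteofp")
  if (!nzchar(script)) stop("bundled ecfp6_bits.py not found")
  inp <- tempfile(fileext = ".tsv")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste(molecules$molecule_id, molecules$smiles, sep = "\t"), inp)
  out <- suppressWarnings(
    system2(py, c(shQuote(script), shQuote(inp), n_bits, radius),
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("ECFP6 backend failed (exit ", status, ")")
  parts <- strsplit(out, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  ok <- vapply(parts, `[`, character(1), 2) == "OK"
  bad <- ids[!ok]
  if (length(bad))
    stop("unparseable SMILES for molecule_id: ", paste(bad, collapse = ", "))
  fps <- matrix(0L, nrow = length(ids), ncol = n_bits,
                dimnames = list(ids, paste0("mbit", seq_len(n_bits) - 1L)))
  for (i in seq_along(parts)) {
    bits <- parts[[i]][3]
    if (nzchar(bits))
      fps[i, as.integer(strsplit(bits, " ", fixed = TRUE)[[1]]) + 1L] <- 1L
  }
  note <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "",
                 character(1))
  list(fps = fps[molecules$molecule_id, , drop = FALSE],
       report = data.frame(molecule_id = ids, status = "ok", note = note,
                           stringsAsFactors = FALSE))
}

#' Tanimoto similarity of two binary fingerprint vectors
#'
#' @param a,b Binary 0/1 vectors of equal length.
#' @return `|A intersect B| / |A union B|` over on-bit positions.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) stop("Tanimoto undefined: both vectors empty")
  inter / uni
}

#' Read a SMILES table (TSV/CSV with molecule_id, smiles columns)
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return data.frame with `molecule_id`, `smiles`.
#' @export
read_smiles_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!all(c("molecule_id", "smiles") %in% names(df)))
    stop("SMILES table needs columns molecule_id, smiles")
  df
}
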