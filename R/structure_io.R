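## Reading and writing protein structures.
##
## A ProteinStructure is a single selected chain of ATOM records with
## one-letter residue codes and Angstrom coordinates. Parsing delegates the
## PDB format itself to bio3d; chain selection, altloc resolution and
## residue-code normalization are applied here.

# Common nonstandard residues mapped to a parent one-letter code.
# Truly unknown codes are skipped with a warning, never invented.
nonstandard_map <- c(
  MSE = "M", SEC = "C", SEP = "S", TPO = "T", PTR = "Y",
  CSO = "C", HYP = "P", MLY = "K", HSD = "H", HSE = "H", HSP = "H"
)

residue_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  sub <- resid %in% names(nonstandard_map)
  out[sub] <- nonstandard_map[resid[sub]]
  out
}

#' Construct a ProteinStructure
#'
#' @param atoms data.frame with columns `serial`, `atom_name`,
#'   `residue_code` (one-letter), `residue_number`, `chain_id`, `x`, `y`,
#'   `z`, and optionally `altloc`, `occupancy`.
#' @param structure_id Identifier for the structure.
#' @param source One of `"alphafold"`, `"experimental"`, `"synthetic"`.
#' @return An object of class `ProteinStructure`.
#' @export
protein_structure <- function(atoms, structure_id,
                              source = c("synthetic", "alphafold", "experimental")) {
  source <- match.arg(source)
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  needed <- c("serial", "atom_name", "residue_code", "residue_number",
              "chain_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (length(unique(atoms$chain_id)) != 1)
    stop("all atoms must share one chain_id")
  if (!all(atoms$residue_code %in% the20))
    stop("residue codes must be one-letter standard amino-acid codes")
  codes <- tapply(atoms$residue_code, atoms$residue_number,
                  function(v) length(unique(v)))
  if (any(codes > 1))
    stop("a residue_number maps to more than one residue code")
  if (is.null(atoms$altloc)) atoms$altloc <- NA_character_
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  rownames(atoms) <- NULL
  structure(
    list(structure_id = as.character(structure_id), source = source,
         chain_id = as.character(atoms$chain_id[1]), atoms = atoms),
    class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat("ProteinStructure", x$structure_id,
      sprintf("[%s, chain %s]: %d atoms, %d residues\n",
              x$source, x$chain_id, nrow(x$atoms), length(residues(x))))
  invisible(x)
}

#' Residue map of a structure
#'
#' @param structure A `ProteinStructure`.
#' @return Named character vector: one-letter codes named by residue number.
#' @export
residues <- function(structure) {
  stopifnot(inherits(structure, "ProteinStructure"))
  a <- structure$atoms
  first <- !duplicated(a$residue_number)
  out <- a$residue_code[first]
  names(out) <- a$residue_number[first]
  out[order(as.integer(names(out)))]
}

#' Parse a PDB file or string into a single-chain ProteinStructure
#'
#' Only polymer ATOM records are kept: HETATM records, waters and other
#' non-polymer entries are excluded. For alternate-location duplicates the
#' conformer with the highest occupancy is kept (ties prefer altloc "A",
#' then first seen). Residue codes are normalized to one-letter; common
#' nonstandard residues (e.g. MSE) map to their parent code and unknown
#' codes are skipped with a warning. Of multi-model files only the first
#' model is read.
#'
#' @param input Path to a PDB file, or a character string of PDB text.
#' @param chain_policy How to select the chain: `"largest_chain"` keeps the
#'   chain with the most distinct residues (ties broken by lexicographically
#'   smallest chain id), `"named_chain"` keeps `chain_name`, `"only_chain"`
#'   requires a single chain.
#' @param chain_name Chain id, required for `chain_policy = "named_chain"`.
#' @param heavy_only Drop hydrogen atoms. Defaults to `FALSE`; predicted
#'   models are heavy-atom only so the default is a no-op for them.
#' @param structure_id Identifier; defaults to the file base name.
#' @param source Provenance tag stored on the result.
#' @return A `ProteinStructure` containing the selected chain.
#' @export
parse_pdb <- function(input,
                      chain_policy = c("largest_chain", "named_chain", "only_chain"),
                      chain_name = NULL, heavy_only = FALSE,
                      structure_id = NULL,
                      source = c("experimental", "alphafold", "synthetic")) {
  chain_policy <- match.arg(chain_policy)
  source <- match.arg(source)
  is_path <- length(input) == 1 && !grepl("\n", input) && file.exists(input)
  if (is_path) {
    path <- input
    if (is.null(structure_id))
      structure_id <- sub("\\.(pdb|ent)$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(input, collapse = "\n"), "\n")), path)
    if (is.null(structure_id)) structure_id <- "structure"
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse failure: ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT", "DOD")), ,
         drop = FALSE]
  if (nrow(a) == 0) stop("PDB parse failure: no polymer ATOM records")
  a$chain[is.na(a$chain)] <- ""
  a$one <- residue_three_to_one(a$resid)
  unknown <- is.na(a$one) | a$one == "X" | !(a$one %in% the20)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " atoms with unknown residue codes: ",
            paste(unique(a$resid[unknown]), collapse = ", "))
    a <- a[!unknown, , drop = FALSE]
  }
  if (nrow(a) == 0) stop("PDB parse failure: no atoms with standard residues")
  if (heavy_only) {
    hyd <- !is.na(a$elesy) & a$elesy == "H"
    hyd <- hyd | (is.na(a$elesy) & grepl("^[0-9]*H", a$elety))
    a <- a[!hyd, , drop = FALSE]
    if (nrow(a) == 0) stop("PDB parse failure: no heavy atoms")
  }
  # altloc resolution: per atom site keep highest occupancy, ties -> 'A',
  # then file order
  occ <- ifelse(is.na(a$o), 1, a$o)
  pref <- ifelse(is.na(a$alt) | a$alt == "A", 0L, 1L)
  site <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  keep_order <- order(site, -occ, pref, seq_len(nrow(a)))
  first_of_site <- !duplicated(site[keep_order])
  keep <- sort(keep_order[first_of_site])
  a <- a[keep, , drop = FALSE]

  chains <- unique(a$chain)
  sel <- switch(chain_policy,
    only_chain = {
      if (length(chains) > 1)
        stop("multiple chains present (", paste(chains, collapse = ", "),
             ") under only_chain policy")
      chains
    },
    named_chain = {
      if (is.null(chain_name)) stop("chain_name required for named_chain")
      if (!chain_name %in% chains)
        stop("chain '", chain_name, "' not present; available: ",
             paste(chains, collapse = ", "))
      chain_name
    },
    largest_chain = {
      nres <- vapply(chains, function(ch)
        length(unique(a$resno[a$chain == ch])), integer(1))
      cand <- chains[nres == max(nres)]
      sort(cand)[1]
    })
  a <- a[a$chain == sel, , drop = FALSE]
  atoms <- data.frame(
    serial = a$eleno, atom_name = a$elety, residue_code = a$one,
    residue_number = a$resno, chain_id = a$chain,
    x = a$x, y = a$y, z = a$z,
    altloc = ifelse(is.na(a$alt), NA_character_, a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE)
  protein_structure(atoms, structure_id = structure_id, source = source)
}

#' Write a ProteinStructure as PDB-format text
#'
#' Round-trips with [parse_pdb()]: coordinates are preserved to the PDB
#' column precision of 0.001 Angstrom.
#'
#' @param structure A `ProteinStructure`.
#' @param path Optional file path; if `NULL` the PDB text is returned.
#' @return Invisibly the path, or the PDB text as a single string.
#' @export
write_pdb <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "ProteinStructure"))
  a <- structure$atoms
  if (nrow(a) == 0) stop("empty structure")
  bad <- abs(c(a$x, a$y, a$z)) >= 10000
  if (any(bad)) stop("coordinates exceed PDB fixed-column width")
  out <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  three <- bio3d::aa123(a$residue_code)
  bio3d::write.pdb(
    file = out,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$residue_number, resid = three,
    eleno = a$serial, elety = a$atom_name, chain = a$chain_id,
    o = a$occupancy, b = rep(0, nrow(a)))
  if (is.null(path)) {
    txt <- paste(readLines(out), collapse = "\n")
    unlink(out)
    return(txt)
  }
  invisible(path)
}
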