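## Synthetic study generator.
##
## Emulates the inputs of a proteo-chemometric Ki study without any
## external downloads: globularly packed Calpha-trace toy structures with
## genuine sequence-nonlocal 3D contacts at 5 A, a sparse binary molecule
## library, and raw activity tables carrying a planted structure-activity
## signal plus the pathologies curation must handle (duplicates, censored
## relations, unit errors).
##
## The signal couples molecule bits to protein structure through motif
## families: targets in one family share a rigid surface motif (hence
## shared fingerprint bits) and share the same molecule-bit response
## weights. A model that reads protein structure can therefore transfer
## activity knowledge between family members; it cannot for a
## motif-orphan target.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a rigid residue motif
#'
#' A cluster of residues with fixed codes and fixed relative geometry,
#' packed in a ball of radius `spread` with residue-like minimum
#' separation, so neighboring motif atoms see distinct (but overlapping)
#' 5 A neighborhoods. Copies of one motif produce identical neighborhood
#' patterns wherever they are placed, because the fingerprint is
#' rigid-motion invariant.
#'
#' @param n_res Number of motif residues (default 16).
#' @param seed Seed.
#' @param spread Radius of the ball containing the motif, in Angstrom.
#' @param min_sep Minimum inter-residue distance (default 3.5 A,
#'   Calpha-like packing).
#' @return List with `codes` (one-letter vector) and `coords`
#'   (`n_res` x 3 matrix, Angstrom).
#' @export
make_motif <- function(n_res = 16L, seed = NULL, spread = 6.0, min_sep = 3.5) {
  with_seed(seed, {
    coords <- matrix(0, n_res, 3)
    for (i in seq_len(n_res)) {
      best <- NULL; best_d <- -Inf
      for (try in seq_len(200)) {
        p <- stats::runif(3, -spread, spread)
        if (sum(p^2) > spread^2) next
        d <- if (i == 1) Inf else
          min(sqrt(colSums((t(coords[seq_len(i - 1), , drop = FALSE]) - p)^2)))
        if (d >= min_sep) { best <- p; break }
        if (d > best_d) { best_d <- d; best <- p }
      }
      coords[i, ] <- best
    }
    list(codes = sample(the20, n_res, replace = TRUE), coords = coords)
  })
}

#' Generate a globular Calpha-trace toy structure
#'
#' A random walk with 3.8 A steps confined to a sphere of radius
#' `3.0 * n_res^(1/3) * packing_radius_scale`, with soft self-avoidance
#' (preferring steps at least 3.4 A from previous atoms). Default
#' compactness guarantees sequence-nonlocal residue contacts at the 5 A
#' fingerprint radius. An optional rigid motif is appended outside the
#' globular core (its neighborhoods then involve motif residues only, so
#' family members sharing the motif share those fingerprint bits
#' exactly).
#'
#' @param n_res Number of core residues (>= 1).
#' @param packing_radius_scale Multiplier on the confinement radius;
#'   1 = default compactness.
#' @param seed Seed.
#' @param motif Optional motif from [make_motif()].
#' @param structure_id Identifier (default "synthetic").
#' @return A `ProteinStructure` (one CA atom per residue, chain "A").
#' @export
make_structure <- function(n_res, packing_radius_scale = 1.0, seed = NULL,
                           motif = NULL, structure_id = "synthetic") {
  stopifnot(n_res >= 1)
  with_seed(seed, {
    rad <- 3.0 * n_res^(1/3) * packing_radius_scale
    pos <- matrix(NA_real_, n_res, 3)
    pos[1, ] <- stats::runif(3, -rad / 4, rad / 4)
    if (n_res > 1) {
      for (i in 2:n_res) {
        dirs <- matrix(stats::rnorm(3 * 30), ncol = 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        cand <- sweep(dirs * 3.8, 2, pos[i - 1, ], `+`)
        inside <- rowSums(cand^2) <= rad^2
        if (!any(inside)) {
          # step back toward the center
          d <- -pos[i - 1, ] / sqrt(sum(pos[i - 1, ]^2))
          pos[i, ] <- pos[i - 1, ] + 3.8 * d
          next
        }
        cand <- cand[inside, , drop = FALSE]
        prev <- pos[seq_len(i - 1), , drop = FALSE]
        mind <- apply(cand, 1, function(p)
          min(sqrt(colSums((t(prev) - p)^2))))
        good <- which(mind >= 3.4)
        pick <- if (length(good)) good[1] else which.max(mind)
        pos[i, ] <- cand[pick, ]
      }
    }
    codes <- sample(the20, n_res, replace = TRUE)
    if (!is.null(motif)) {
      rot <- random_rotation()
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      centre <- u * (rad + 12)  # > 5 A clearance from any core atom
      mc <- motif$coords %*% rot
      mc <- sweep(mc, 2, centre, `+`)
      pos <- rbind(pos, mc)
      codes <- c(codes, motif$codes)
    }
    atoms <- data.frame(
      serial = seq_len(nrow(pos)), atom_name = "CA",
      residue_code = codes, residue_number = seq_len(nrow(pos)),
      chain_id = "A", x = round(pos[, 1], 3), y = round(pos[, 2], 3),
      z = round(pos[, 3], 3), stringsAsFactors = FALSE)
    protein_structure(atoms, structure_id = structure_id, source = "synthetic")
  })
}

#' Substitute a fraction of a structure's residues
#'
#' Emulates sequence divergence between homologous structures: a random
#' fraction of residues receive a different one-letter code while
#' coordinates stay fixed. Neighborhood patterns containing any mutated
#' residue change, so the fingerprint similarity between a template and
#' its mutant decays smoothly with the mutation fraction.
#'
#' @param structure A `ProteinStructure`.
#' @param fraction Fraction of residues to substitute (rounded up).
#' @param seed Seed.
#' @return A `ProteinStructure` with mutated residue codes.
#' @export
mutate_residues <- function(structure, fraction, seed = NULL) {
  stopifnot(inherits(structure, "ProteinStructure"),
            fraction >= 0, fraction <= 1)
  if (fraction == 0) return(structure)
  with_seed(seed, {
    a <- structure$atoms
    res <- unique(a$residue_number)
    pick <- sample(res, ceiling(fraction * length(res)))
    for (r in pick) {
      old <- a$residue_code[a$residue_number == r][1]
      a$residue_code[a$residue_number == r] <- sample(setdiff(the20, old), 1)
    }
    protein_structure(a, structure_id = structure$structure_id,
                      source = structure$source)
  })
}

#' Generate a sparse binary molecule library
#'
#' Random 2048-bit fingerprints with independent on-probability `density`.
#' Columns listed in `causal_bits` are re-sampled at `causal_density`
#' (default 0.5) so the planted signal bits carry variance.
#'
#' @param n Number of molecules.
#' @param density On-probability of a background bit.
#' @param seed Seed.
#' @param n_bits Fingerprint length (default 2048).
#' @param causal_bits Optional 1-based column indices to re-sample.
#' @param causal_density On-probability for causal bits.
#' @return Binary matrix, rows named `MOL0001`, ...
#' @export
make_molecules <- function(n, density = 0.05, seed = NULL, n_bits = 2048L,
                           causal_bits = NULL, causal_density = 0.5) {
  stopifnot(density > 0, density < 1, n >= 0)
  with_seed(seed, {
    m <- matrix(stats::rbinom(n * n_bits, 1L, density),
                nrow = n, ncol = n_bits,
                dimnames = list(sprintf("MOL%04d", seq_len(n)),
                                paste0("mbit", seq_len(n_bits) - 1L)))
    if (!is.null(causal_bits) && n > 0)
      m[, causal_bits] <- stats::rbinom(n * length(causal_bits), 1L,
                                        causal_density)
    m
  })
}

#' Synthetic study configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 20 targets (8 homolog families of two plus 4
#' family-orphans) of 80 residues, 400 molecules, 200 activities per
#' target, measurement noise of 0.05 on the spKi scale (about 0.2 log10
#' units of Ki), and 5% each of censored and duplicated records plus 2%
#' wrong-unit records. Family members are generated as mutated copies
#' (fraction `mutation_rate` of residues substituted) of a shared family
#' template fold, emulating paralogous receptors with conserved
#' structure.
#'
#' @param n_targets Number of protein targets.
#' @param residues_per_target Core residues per toy structure.
#' @param n_molecules Library size.
#' @param activities_per_target Activity records sampled per target.
#' @param packing_radius_scale Structure compactness multiplier.
#' @param family_sizes Integer vector of family sizes summing to
#'   `n_targets`; size-1 families are structural orphans.
#' @param mutation_rate Fraction of template residues substituted in each
#'   family member (default 0.03, i.e. close homologs with Jaccard
#'   fingerprint similarity around 0.5 at the toy scale).
#' @param n_causal Causal molecule bits per family (default 4).
#' @param effect_size Multiplier on the planted interaction weights.
#' @param intercept_spread Half-width of the per-family baseline potency
#'   offset around 0.5 (default 0.12; 0 isolates the pure
#'   molecule-protein interaction signal).
#' @param noise_sd Gaussian noise sd on the spKi scale.
#' @param censor_fraction Fraction of active records emitted as "<"
#'   censored observations.
#' @param duplicate_fraction Fraction of records duplicated with a
#'   perturbed value and later year.
#' @param unit_error_fraction Fraction of records given non-concentration
#'   units (to exercise exclusion).
#' @param mol_density Background molecule bit density.
#' @param seed Seed for the whole study.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_targets = 20L, residues_per_target = 80L,
                             n_molecules = 400L, activities_per_target = 200L,
                             packing_radius_scale = 1.0,
                             family_sizes = NULL, mutation_rate = 0.03,
                             n_causal = 4L,
                             effect_size = 1.0, intercept_spread = 0.12,
                             noise_sd = 0.05,
                             censor_fraction = 0.05,
                             duplicate_fraction = 0.05,
                             unit_error_fraction = 0.02,
                             mol_density = 0.05, seed = 1L) {
  if (is.null(family_sizes)) {
    n_pairs <- floor(n_targets * 0.4)
    family_sizes <- c(rep(2L, n_pairs), rep(1L, n_targets - 2L * n_pairs))
  }
  stopifnot(sum(family_sizes) == n_targets,
            mutation_rate >= 0, mutation_rate <= 1,
            all(c(censor_fraction, duplicate_fraction, unit_error_fraction) >= 0),
            all(c(censor_fraction, duplicate_fraction, unit_error_fraction) <= 1),
            noise_sd >= 0, n_molecules > 0, activities_per_target > 0)
  structure(as.list(environment()), class = "SyntheticConfig")
}

#' Generate the planted interaction model
#'
#' Each family receives its own intercept (a baseline potency offset
#' around 0.5, emulating targets of differing mean druggability) and its
#' own set of causal molecule bits with signed weights; the true potency
#' of (molecule, target) is `clamp01(family intercept + sum of weights
#' over the molecule's on causal bits)`. Signs are balanced within each
#' family (half activating, half deactivating) so the response
#' distribution stays centered in the score range instead of saturating
#' a family at 0 or 1 — a saturated family would be dropped by the
#' variability filter during curation anyway.
#'
#' @param family_ids Character vector of family ids.
#' @param n_causal Causal bits per family (default 4).
#' @param effect_size Weight multiplier.
#' @param n_bits Molecule fingerprint length.
#' @param seed Seed.
#' @param weight_range Magnitude range of the causal weights.
#' @param intercept_spread Half-width of the uniform family-intercept
#'   offset around 0.5.
#' @return A `PlantedModel`: `intercepts` (named per family), `terms`
#'   (per-family data.frames with `bit`, `weight`), `causal_bits` (all
#'   bits used).
#' @export
planted_model <- function(family_ids, n_causal = 4L, effect_size = 1.0,
                          n_bits = 2048L, seed = NULL,
                          weight_range = c(0.2, 0.35),
                          intercept_spread = 0.12) {
  with_seed(seed, {
    pool <- sample.int(n_bits, length(family_ids) * n_causal)
    terms <- list()
    intercepts <- stats::setNames(
      0.5 + stats::runif(length(family_ids), -intercept_spread,
                         intercept_spread), family_ids)
    for (i in seq_along(family_ids)) {
      bits <- pool[seq((i - 1) * n_causal + 1, i * n_causal)]
      signs <- sample(rep_len(c(-1, 1), n_causal))
      w <- effect_size * signs *
        stats::runif(n_causal, weight_range[1], weight_range[2])
      terms[[family_ids[i]]] <- data.frame(bit = bits, weight = w)
    }
    structure(list(intercepts = intercepts, terms = terms,
                   causal_bits = pool),
              class = "PlantedModel")
  })
}

#' True spKi under the planted model
#'
#' @param planted A `PlantedModel`.
#' @param mol_fps Binary molecule matrix.
#' @param family Family id (one string).
#' @return Vector of true spKi, one per molecule row.
#' @export
planted_spki <- function(planted, mol_fps, family) {
  t <- planted$terms[[family]]
  if (is.null(t)) stop("unknown family: ", family)
  clamp01(planted$intercepts[[family]] +
            as.numeric(mol_fps[, t$bit, drop = FALSE] %*% t$weight))
}

#' Emit a raw activity table from the planted model
#'
#' Noisy true potencies are converted to Ki through the inverse spKi
#' transform and written as ChEMBL-like rows. Potencies at the branch
#' boundaries are emitted explicitly (Ki 0.5 nM at score 1; an inactive
#' ">" record at 10,000 nM at score 0) since the inverse transform is not
#' unique there. Fractions of records are censored ("<" at an inflated
#' value), duplicated (perturbed within one order of magnitude, later
#' year) or spoiled with wrong units.
#'
#' @param mol_fps Binary molecule matrix.
#' @param target_families Named character vector: target id -> family id.
#' @param planted A `PlantedModel`.
#' @param config A `SyntheticConfig`.
#' @return List with `records` (raw activity data.frame) and `truth`
#'   (`molecule_id`, `target_id`, `true_spki`, `noisy_spki`).
#' @export
plant_activities <- function(mol_fps, target_families, planted, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(config$seed + 211L, {
    recs <- list(); truth <- list()
    for (tid in names(target_families)) {
      fam <- target_families[[tid]]
      nact <- min(config$activities_per_target, nrow(mol_fps))
      mols <- sample(rownames(mol_fps), nact)
      tru <- planted_spki(planted, mol_fps[mols, , drop = FALSE], fam)
      noisy <- clamp01(tru + stats::rnorm(nact, 0, config$noise_sd))
      year <- sample(2000:2020, nact, replace = TRUE)
      rel <- rep("=", nact); val <- numeric(nact)
      inact <- noisy <= 0
      ceil1 <- noisy >= 1
      mid <- !inact & !ceil1
      rel[inact] <- ">"
      val[inact] <- 10000
      val[ceil1] <- 0.5
      val[mid] <- spki_to_ki(noisy[mid])
      # censored active records: "<" at a value above the true Ki
      cen <- mid & stats::runif(nact) < config$censor_fraction
      rel[cen] <- "<"
      val[cen] <- val[cen] * 10^stats::runif(sum(cen), 0.1, 0.5)
      df <- data.frame(
        molecule_id = mols, target_id = tid, activity_type = "Ki",
        relation = rel, value = val, units = "nM",
        comment = NA_character_, year = year, stringsAsFactors = FALSE)
      # unit noise: some records converted losslessly to uM, a few spoiled
      to_uM <- stats::runif(nact) < 0.1
      df$value[to_uM] <- df$value[to_uM] / 1e3
      df$units[to_uM] <- "uM"
      spoil <- stats::runif(nact) < config$unit_error_fraction
      df$units[spoil] <- "%"
      # duplicates: eq records re-measured within one order of magnitude
      dup_idx <- which(mid & !cen & !spoil &
                         stats::runif(nact) < config$duplicate_fraction)
      if (length(dup_idx)) {
        d2 <- df[dup_idx, , drop = FALSE]
        d2$value <- d2$value * 10^stats::runif(length(dup_idx), -0.3, 0.3)
        d2$year <- d2$year + 1L
        df <- rbind(df, d2)
      }
      recs[[tid]] <- df
      truth[[tid]] <- data.frame(molecule_id = mols, target_id = tid,
                                 true_spki = tru, noisy_spki = noisy,
                                 stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, recs); rownames(recs) <- NULL
    truth <- do.call(rbind, truth); rownames(truth) <- NULL
    list(records = recs, truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Builds homolog families (one template fold per family, members as
#' lightly mutated copies), protein fingerprints, the molecule library,
#' the planted interaction model and the raw activity table, all
#' deterministically from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List: `config`, `families` (named target -> family id),
#'   `structures`, `fingerprints`, `molecules`, `planted`, `records`,
#'   `truth`.
#' @export
synthetic_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  fam_ids <- sprintf("FAM%02d", seq_along(config$family_sizes))
  families <- rep(fam_ids, config$family_sizes)
  targets <- sprintf("TGT%02d", seq_len(config$n_targets))
  names(families) <- targets
  templates <- lapply(seq_along(fam_ids), function(i)
    make_structure(config$residues_per_target,
                   packing_radius_scale = config$packing_radius_scale,
                   seed = config$seed + 700L + i,
                   structure_id = fam_ids[i]))
  names(templates) <- fam_ids
  structures <- lapply(seq_along(targets), function(i) {
    st <- mutate_residues(templates[[families[[i]]]],
                          fraction = config$mutation_rate,
                          seed = config$seed + 900L + i)
    st$structure_id <- targets[i]
    st
  })
  names(structures) <- targets
  fps <- lapply(structures, fingerprint)
  molecules <- make_molecules(
    config$n_molecules, density = config$mol_density,
    seed = config$seed + 97L)
  planted <- planted_model(fam_ids, n_causal = config$n_causal,
                           effect_size = config$effect_size,
                           intercept_spread = config$intercept_spread,
                           seed = config$seed + 131L)
  # causal bits must vary in the library to carry signal
  molecules <- with_seed(config$seed + 98L, {
    molecules[, planted$causal_bits] <-
      stats::rbinom(nrow(molecules) * length(planted$causal_bits), 1L, 0.5)
    molecules
  })
  acts <- plant_activities(molecules, families, planted, config)
  list(config = config, families = families, structures = structures,
       fingerprints = fps, molecules = molecules, planted = planted,
       records = acts$records, truth = acts$truth)
}
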