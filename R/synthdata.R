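# Synthetic bioassay generator: labelled feature tables with the pipeline's
# 8 + 24 + 147 block structure, and small valid molecule files, so that
# training, screening and evaluation are testable without any download.
# The defaults emulate a PubChem-style confirmatory screen: strong class
# imbalance (12.5% active, echoing a 37,055-of-296,456 actives assay) and
# sparse fingerprint bits (base on-probability 0.1).

#' Specification of a synthetic bioassay
#'
#' @param n number of compounds (>= 2).
#' @param active_fraction fraction of actives in (0, 1); the active count is
#'   exactly `ceiling(n * active_fraction)`. Default 0.125.
#' @param n_informative number of signal-carrying descriptor columns
#'   (<= 179). Default 10.
#' @param effect_size between-class shift: informative continuous columns
#'   are shifted by `effect_size * noise_sd` for actives; informative bit
#'   columns have their on-probability raised by
#'   `min(effect_size * 0.1, 0.4)`. Default 1.
#' @param noise_sd standard deviation of the continuous columns. Default 1.
#' @param seed integer seed; the table is a pure function of the spec.
#' @return object of class `assay_spec`.
#' @export
assay_spec <- function(n, active_fraction = 0.125, n_informative = 10L,
                       effect_size = 1, noise_sd = 1, seed = 1L) {
  stopifnot(n >= 2, active_fraction > 0, active_fraction < 1,
            n_informative >= 1, n_informative <= 179,
            effect_size >= 0, noise_sd > 0)
  n_active <- as.integer(ceiling(n * active_fraction))
  if (n_active == 0 || n_active == n) {
    stop("degenerate spec: a single class would be generated")
  }
  structure(list(n = as.integer(n), active_fraction = active_fraction,
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "assay_spec")
}

#' Generate a synthetic bioassay feature table
#'
#' Produces `spec$n` rows by 179 columns honouring the descriptor block
#' structure: columns 1..32 are Gaussian (continuous blocks), columns
#' 33..179 are Bernoulli bits with base on-probability 0.1. Exactly
#' `ceiling(n * active_fraction)` rows are active, in random positions. The
#' informative columns are chosen deterministically from the seed; actives
#' get the effect-size shift described in [assay_spec()]. The output is
#' reproducible given the spec and leaves the caller's RNG state untouched.
#'
#' @param spec an [assay_spec()].
#' @return a labelled [feature_table()] with 179 descriptor columns.
#' @export
generate_assay <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n
    n_active <- as.integer(ceiling(n * spec$active_fraction))
    labels <- integer(n)
    labels[sample.int(n, n_active)] <- 1L
    info <- sort(sample.int(179L, spec$n_informative))

    m <- matrix(0, n, 179L)
    for (j in 1:32) m[, j] <- rnorm(n, 0, spec$noise_sd)
    for (j in 33:179) m[, j] <- rbinom(n, 1L, 0.1)

    act <- labels == 1L
    shift_bits <- min(spec$effect_size * 0.1, 0.4)
    for (j in info) {
      if (j <= 32) {
        m[act, j] <- m[act, j] + spec$effect_size * spec$noise_sd
      } else {
        m[act, j] <- rbinom(sum(act), 1L, min(0.1 + shift_bits, 1))
      }
    }
    colnames(m) <- descriptor_names()
    ft <- feature_table(m, ids = sprintf("CMPD%05d", seq_len(n)),
                        labels = labels)
    attr(ft, "informative_columns") <- info
    ft
  })
}

# ~50 small drug-like parent structures (valid SMILES, all parseable by
# parse_smiles); each ends at an atom that can accept further single bonds,
# so methyl-chain decorations stay valid.
.mol_library <- c(
  "c1ccccc1O", "c1ccccc1N", "c1ccccc1C(=O)O", "c1ccccc1C(=O)N",
  "c1ccccc1S(=O)(=O)N", "c1ccc(cc1)CC(N)C(=O)O", "c1ccc2ccccc2c1",
  "c1ccncc1", "c1ccc(nc1)N", "c1cnc2[nH]ccc2c1", "c1coc(c1)C(=O)O",
  "c1csc(c1)C(=O)N", "c1cc[nH]c1", "c1cnccn1", "c1cncnc1N",
  "CC(=O)Nc1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "CN(C)c1ccccc1",
  "COc1ccccc1O", "CCOC(=O)c1ccccc1N", "NC(=O)c1ccccc1O",
  "Clc1ccccc1C(=O)O", "Brc1ccccc1N", "Fc1ccc(cc1)C(=O)O",
  "OC(=O)CCc1ccccc1", "OCC(O)c1ccccc1", "NCCc1ccccc1",
  "NCCc1ccc(O)cc1", "CC(N)Cc1ccccc1", "OC(=O)c1ccc(O)cc1",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CN1CCCC1", "C1CCNCC1", "C1CCOCC1",
  "O=C1CCCCC1", "OC1CCCCC1", "NC1CCCCC1", "CC(=O)C", "CC(O)C",
  "CCOCC", "CCSC", "CC(=O)OC", "NC(=O)C", "OC(=O)C(N)C",
  "OC(=O)C(N)CC(=O)O", "CNC(=O)C", "CC#N", "OCCN", "OCCOC", "NCCN",
  "[NH3+]CCC([O-])=O", "Cn1ccnc1"
)

#' Write synthetic molecule fixture files
#'
#' Draws `n` small drug-like structures from a built-in library of ~50
#' parseable SMILES, decorated (when `n` exceeds the library) with short
#' methyl-chain extensions so every structure stays valid and distinct, and
#' writes them as both an SDF and a SMILES file with ids and a synthetic
#' activity tag (`"ACTIVITY"`, actives drawn with probability 0.3). The
#' outputs are byte-identical for a fixed seed.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed.
#' @param path output path prefix; `<path>.sdf` and `<path>.smi` are written.
#' @return invisibly, a list with the two file paths and the molecule list.
#' @export
generate_molecules <- function(n, seed, path) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    base <- .mol_library
    smiles <- character(n)
    for (i in seq_len(n)) {
      k <- (i - 1L) %% length(base) + 1L
      deco <- (i - 1L) %/% length(base)  # 0 for the first pass, then chains
      smiles[i] <- paste0(base[k], strrep("C", deco))
    }
    ids <- sprintf("SYN%05d", seq_len(n))
    active <- runif(n) < 0.3
    mols <- lapply(seq_len(n), function(i) {
      rec <- parse_smiles(smiles[i], id = ids[i])
      rec$activity <- if (active[i]) "active" else "inactive"
      rec$source_index <- i
      rec
    })
    sdf_path <- paste0(path, ".sdf")
    smi_path <- paste0(path, ".smi")
    write_sdf(mols, sdf_path, activity_tag = "ACTIVITY")
    writeLines(paste(smiles, ids), smi_path, useBytes = TRUE)
    invisible(list(sdf = sdf_path, smi = smi_path, molecules = mols))
  })
}
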