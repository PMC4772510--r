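# 179-descriptor featurization with the fixed block structure
#   [1, 8]    drug-likeness panel        (DL_*)
#   [9, 32]   Burden-matrix eigenvalues  (BCUT_*)  -- 24 continuous values
#   [33, 179] pharmacophore-pair bits    (PF_*)    -- 147 bits
#
# The block structure (8 + 24 + 147) is the contract; the individual
# definitions inside each block are a documented structural stand-in for the
# proprietary PowerMV/CDK scheme they emulate (see the methods vignette).
# Everything is computed on the implicit-hydrogen heavy-atom graph.

.pf_classes <- c("don", "acc", "aro", "hyd", "pos", "neg")
.pf_bins <- 7L  # topological distances 1..6 and >= 7

#' Names of the 179 descriptors
#'
#' Stable column names with block prefixes: `DL_` (8 drug-likeness
#' properties: molecular weight, crude logP, H-bond donors, H-bond
#' acceptors, rotatable bonds, topological polar surface area, ring count,
#' heavy-atom count), `BCUT_` (lowest/highest four eigenvalues of the Burden
#' connectivity matrix under atomic-mass, electronegativity and
#' covalent-radius weightings: 3 x 8 = 24), and `PF_` (21 unordered pairs of
#' 6 pharmacophore classes -- donor, acceptor, aromatic, hydrophobe,
#' positive, negative -- times 7 topological-distance bins = 147 bits).
#'
#' @return character vector of length 179.
#' @export
descriptor_names <- function() {
  dl <- paste0("DL_", c("MW", "LogP", "HBD", "HBA", "RotB", "TPSA",
                        "Rings", "HeavyAtoms"))
  bcut <- as.vector(vapply(c("mass", "eneg", "rcov"), function(w) {
    paste0("BCUT_", w, "_", c(paste0("lo", 1:4), paste0("hi", 1:4)))
  }, character(8)))
  pf <- character(0)
  for (i in seq_along(.pf_classes)) {
    for (j in i:length(.pf_classes)) {
      pf <- c(pf, paste0("PF_", .pf_classes[i], "_", .pf_classes[j], "_b",
                         seq_len(.pf_bins)))
    }
  }
  c(dl, bcut, pf)
}

# --- graph utilities -------------------------------------------------------

# all-pairs shortest path lengths in bonds (BFS per atom); Inf if unreachable
.topo_distances <- function(natoms, bonds) {
  adj <- vector("list", natoms)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], bonds$a2[b])
      adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], bonds$a1[b])
    }
  }
  D <- matrix(Inf, natoms, natoms)
  for (s in seq_len(natoms)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(D[s, v])) {
          D[s, v] <- D[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  D
}

# a bond lies in a ring iff its endpoints stay connected after its removal
.ring_bonds <- function(natoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0) return(logical(0))
  in_ring <- logical(nb)
  for (b in seq_len(nb)) {
    keep <- bonds[-b, , drop = FALSE]
    D <- .topo_distances(natoms, keep)
    in_ring[b] <- is.finite(D[bonds$a1[b], bonds$a2[b]])
  }
  in_ring
}

.n_components <- function(natoms, bonds) {
  D <- .topo_distances(natoms, bonds)
  comp <- integer(natoms)
  k <- 0L
  for (a in seq_len(natoms)) {
    if (comp[a] == 0L) {
      k <- k + 1L
      comp[is.finite(D[a, ])] <- k
    }
  }
  k
}

# --- drug-likeness block ---------------------------------------------------

# Crude atom-contribution logP (octanol/water). A documented stand-in with
# the right qualitative behaviour (aromatics and halogens lipophilic,
# heteroatoms and polar hydrogens hydrophilic); not a reproduction of any
# published fragment scheme.
.logp_contrib <- c(B = 0.05, C = 0.17, N = -0.72, O = -0.64, F = 0.22,
                   Si = 0.40, P = -0.50, S = 0.28, Cl = 0.65, Se = 0.30,
                   Br = 0.88, I = 1.12)
.logp_aromatic_c <- 0.34
.logp_polar_h <- -0.32

# Reduced Ertl-style TPSA contributions for N and O environments (S and P
# omitted, as in the original default). Values in Angstrom^2.
.tpsa_atom <- function(symbol, charge, aromatic, nH, has_double, has_triple) {
  if (symbol == "N") {
    if (aromatic) return(if (nH >= 1) 15.79 else 12.89)
    if (charge > 0) {
      return(switch(as.character(min(nH, 3L)),
                    "0" = 0.00, "1" = 4.44, "2" = 16.61, "3" = 27.64))
    }
    if (has_triple) return(23.79)
    if (has_double) return(12.36)
    return(switch(as.character(min(nH, 2L)),
                  "0" = 3.24, "1" = 12.03, "2" = 26.02))
  }
  if (symbol == "O") {
    if (aromatic) return(13.14)
    if (charge < 0) return(23.06)
    if (has_double) return(17.07)
    return(if (nH >= 1) 20.23 else 9.23)
  }
  0
}

.drug_likeness_block <- function(mol, ring_bond, D) {
  at <- mol$atoms; bd <- mol$bonds
  n <- nrow(at)
  mw <- sum(.elem_prop(at$symbol, "mass")) + 1.008 * sum(at$nH)

  deg <- integer(n)
  has_double <- logical(n); has_triple <- logical(n)
  neighbor_NO <- logical(n)
  if (nrow(bd) > 0) {
    for (b in seq_len(nrow(bd))) {
      i <- bd$a1[b]; j <- bd$a2[b]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      if (bd$order[b] == 2) has_double[c(i, j)] <- TRUE
      if (bd$order[b] == 3) has_triple[c(i, j)] <- TRUE
      if (at$symbol[j] %in% c("N", "O")) neighbor_NO[i] <- TRUE
      if (at$symbol[i] %in% c("N", "O")) neighbor_NO[j] <- TRUE
    }
  }
  is_NO <- at$symbol %in% c("N", "O")
  hbd <- sum(is_NO & at$nH >= 1)
  hba <- sum(is_NO)

  logp <- sum(ifelse(at$symbol == "C" & at$aromatic, .logp_aromatic_c,
                     .logp_contrib[at$symbol])) +
    .logp_polar_h * sum(at$nH[is_NO])

  rotb <- 0L
  if (nrow(bd) > 0) {
    rotb <- sum(bd$order == 1 & !ring_bond &
                  deg[bd$a1] >= 2 & deg[bd$a2] >= 2)
  }

  tpsa <- sum(vapply(seq_len(n), function(a) {
    .tpsa_atom(at$symbol[a], at$charge[a], at$aromatic[a], at$nH[a],
               has_double[a], has_triple[a])
  }, numeric(1)))

  rings <- nrow(bd) - n + .n_components(n, bd)  # cyclomatic ring count

  c(mw, logp, hbd, hba, rotb, tpsa, rings, n)
}

# --- BCUT block ------------------------------------------------------------

# Burden connectivity matrix: diagonal = atomic property, off-diagonal
# 0.1 * bond order for bonded pairs (0.15 for aromatic bonds), 0.001 for
# non-bonded pairs. The 4 lowest and 4 highest eigenvalues under each of the
# mass / electronegativity / covalent-radius weightings give 24 descriptors.
.bcut_block <- function(mol) {
  at <- mol$atoms; bd <- mol$bonds
  n <- nrow(at)
  out <- numeric(0)
  for (w in c("mass", "eneg", "rcov")) {
    B <- matrix(0.001, n, n)
    diag(B) <- .elem_prop(at$symbol, w)
    if (nrow(bd) > 0) {
      for (b in seq_len(nrow(bd))) {
        B[bd$a1[b], bd$a2[b]] <- B[bd$a2[b], bd$a1[b]] <- 0.1 * bd$order[b]
      }
    }
    ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
    lo <- ev[pmin(1:4, n)]
    hi <- ev[pmax(n - (1:4) + 1L, 1L)]
    out <- c(out, lo, hi)
  }
  out
}

# --- pharmacophore-pair fingerprint ---------------------------------------

# Atom-level pharmacophore classes (simple topological definitions):
#   don: N/O bearing at least one hydrogen
#   acc: N/O with non-positive formal charge
#   aro: atom flagged aromatic
#   hyd: carbon with no N/O neighbour, or S/Cl/Br/I
#   pos: formal charge > 0, or a non-aromatic amine N (all single bonds)
#   neg: formal charge < 0, or an acidic O-H (O-H on an atom that also
#        carries a double-bonded O: carboxylic/sulfonic/phosphoric pattern)
.pf_atom_classes <- function(mol) {
  at <- mol$atoms; bd <- mol$bonds
  n <- nrow(at)
  neighbor_NO <- logical(n)
  all_single <- rep(TRUE, n)
  dbl_O_on <- logical(n)  # atom carries a double bond to an O
  if (nrow(bd) > 0) {
    for (b in seq_len(nrow(bd))) {
      i <- bd$a1[b]; j <- bd$a2[b]
      if (at$symbol[j] %in% c("N", "O")) neighbor_NO[i] <- TRUE
      if (at$symbol[i] %in% c("N", "O")) neighbor_NO[j] <- TRUE
      if (bd$order[b] != 1) all_single[c(i, j)] <- FALSE
      if (bd$order[b] == 2 && at$symbol[j] == "O") dbl_O_on[i] <- TRUE
      if (bd$order[b] == 2 && at$symbol[i] == "O") dbl_O_on[j] <- TRUE
    }
  }
  acidic_OH <- logical(n)
  if (nrow(bd) > 0) {
    for (b in seq_len(nrow(bd))) {
      i <- bd$a1[b]; j <- bd$a2[b]
      if (at$symbol[i] == "O" && at$nH[i] >= 1 && dbl_O_on[j]) acidic_OH[i] <- TRUE
      if (at$symbol[j] == "O" && at$nH[j] >= 1 && dbl_O_on[i]) acidic_OH[j] <- TRUE
    }
  }
  is_NO <- at$symbol %in% c("N", "O")
  cbind(
    don = is_NO & at$nH >= 1,
    acc = is_NO & at$charge <= 0,
    aro = at$aromatic,
    hyd = (at$symbol == "C" & !neighbor_NO) |
      at$symbol %in% c("S", "Cl", "Br", "I"),
    pos = at$charge > 0 | (at$symbol == "N" & !at$aromatic & all_single),
    neg = at$charge < 0 | acidic_OH
  )
}

.pf_block <- function(mol, D) {
  cls <- .pf_atom_classes(mol)
  n <- nrow(cls)
  bits <- integer(21L * .pf_bins)
  k <- 0L
  for (i in seq_along(.pf_classes)) {
    for (j in i:length(.pf_classes)) {
      ai <- which(cls[, i]); aj <- which(cls[, j])
      present <- logical(.pf_bins)
      if (length(ai) > 0 && length(aj) > 0) {
        d <- D[ai, aj, drop = FALSE]
        d <- d[is.finite(d) & d >= 1]
        if (length(d) > 0) {
          bin <- pmin(d, .pf_bins)
          present[unique(bin)] <- TRUE
        }
      }
      bits[k + seq_len(.pf_bins)] <- as.integer(present)
      k <- k + .pf_bins
    }
  }
  bits
}

# --- public surface --------------------------------------------------------

#' Compute the 179-descriptor vector for one molecule
#'
#' Deterministic, purely topological featurization of the heavy-atom graph;
#' the same structure always yields the same vector regardless of input
#' format or atom ordering within symmetry.
#'
#' @param mol a [molecule_record()].
#' @return numeric vector of length 179, named by [descriptor_names()].
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molecule_record"))
  block <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("descriptor computation failed for molecule '", mol$id,
           "' in block '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  D <- block("graph", .topo_distances(nrow(mol$atoms), mol$bonds))
  ring_bond <- block("graph", .ring_bonds(nrow(mol$atoms), mol$bonds))
  v <- c(block("drug-likeness", .drug_likeness_block(mol, ring_bond, D)),
         block("BCUT", .bcut_block(mol)),
         block("pharmacophore", .pf_block(mol, D)))
  names(v) <- descriptor_names()
  stopifnot(length(v) == 179L, all(is.finite(v)))
  v
}

#' Featurize a list of molecules into a feature table
#'
#' Row i of the result corresponds to `mols[[i]]`. Labels are populated iff
#' every molecule carries an activity label; a mix of labelled and
#' unlabelled molecules yields an unlabelled table with a warning.
#'
#' @param mols non-empty list of [molecule_record()] objects.
#' @return a [feature_table()].
#' @export
featurize <- function(mols) {
  if (length(mols) == 0) stop("cannot featurize an empty molecule list")
  m <- t(vapply(mols, compute_descriptors, numeric(179L)))
  colnames(m) <- descriptor_names()
  ids <- vapply(mols, function(x) x$id, character(1))
  acts <- vapply(mols, function(x) x$activity, character(1))
  labels <- NULL
  if (all(!is.na(acts))) {
    labels <- as.integer(acts == "active")
  } else if (any(!is.na(acts))) {
    warning("mixed labelled/unlabelled molecules; labels omitted",
            call. = FALSE)
  }
  feature_table(m, ids = ids, labels = labels)
}
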