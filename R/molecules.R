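# Molecule input layer: a minimal 2D molecular-graph model plus SMILES and
# MDL SDF (V2000) readers/writers. No cheminformatics toolkit is assumed:
# descriptors here are topological (2D), so all that is needed from a
# structure file is the heavy-atom graph (element, formal charge,
# aromaticity, hydrogen count) -- which these parsers recover.
#
# Scope: the organic subset + common hetero elements, single/double/triple/
# aromatic bonds, branches, ring closures (including %nn), bracket atoms with
# charge and explicit H counts. Stereo markers are accepted and ignored
# (descriptors are 2D). Wildcards, isotope-dependent properties and radicals
# are out of scope; such inputs fail with an informative error and are
# skipped (with a warning) by the file readers.

.element_data <- local({
  sym <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I")
  data.frame(
    symbol = sym,
    mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974,
             32.06, 35.453, 78.971, 79.904, 126.904),
    # Pauling electronegativity
    eneg = c(2.20, 2.04, 2.55, 3.04, 3.44, 3.98, 1.90, 2.19, 2.58, 3.16,
             2.55, 2.96, 2.66),
    # covalent radius, Angstrom
    rcov = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.11, 1.07, 1.05, 1.02,
             1.20, 1.20, 1.39),
    stringsAsFactors = FALSE
  )
})

# Default valences used for implicit-hydrogen completion; multi-valent
# elements list the alternatives in increasing order. Neutral N is fixed at
# 3 (the usual toolkit convention; legacy pentavalent nitro notation is not
# supported -- write the charge-separated form instead).
.element_valences <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Se = c(2, 4, 6), Br = 1, I = 1
)

.elem_prop <- function(symbols, prop) {
  i <- match(symbols, .element_data$symbol)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(symbols[is.na(i)]), collapse = ", "))
  }
  .element_data[[prop]][i]
}

# Implicit hydrogen count from the effective valence rule: formal charge
# shifts the valence alternatives (N+ -> 4, O- -> 1, ...); the smallest
# alternative >= ceiling(bond-order sum) is filled up with hydrogens.
.implicit_h <- function(symbol, charge, bond_order_sum) {
  vals <- .element_valences[[symbol]]
  if (is.null(vals)) stop("unsupported element: ", symbol)
  vals <- vals + charge
  need <- ceiling(bond_order_sum - 1e-9)
  vals <- vals[vals >= need]
  if (length(vals) == 0L) 0L else as.integer(vals[1] - need)
}

#' Construct a molecule record
#'
#' A molecule record is the unit the featurizer consumes: a heavy-atom graph
#' with element symbols, formal charges, aromatic flags and (explicit +
#' implicit) hydrogen counts, plus an identifier and an optional binary
#' activity label.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `symbol`, `charge`, `aromatic`, `nH`.
#' @param bonds data.frame with columns `a1`, `a2`, `order` (aromatic bonds
#'   carry order 1.5); may have zero rows for single-atom molecules.
#' @param activity optional `"active"`/`"inactive"`, or `NA` when unlabelled.
#' @param source_index ordinal position in the input file, if any.
#' @return an object of class `molecule_record`.
#' @export
molecule_record <- function(id, atoms, bonds, activity = NA_character_,
                            source_index = NA_integer_) {
  stopifnot(nrow(atoms) >= 1)
  if (!is.na(activity) && !activity %in% c("active", "inactive")) {
    stop("activity must be 'active', 'inactive' or NA")
  }
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$a1 >= 1), all(bonds$a2 <= nrow(atoms)),
              all(bonds$a1 != bonds$a2))
  }
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         activity = activity, source_index = source_index),
    class = "molecule_record"
  )
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record '%s': %d heavy atoms, %d bonds%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              if (is.na(x$activity)) "" else paste0(", ", x$activity)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# SMILES

#' Parse a single SMILES string
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I and their
#' aromatic lowercase forms), bracket atoms with charge and explicit hydrogen
#' counts, branches, ring closures (digits and `%nn`), bond symbols
#' `- = # :`, directional bonds (`/`, `\\`, read as single), and dot
#' disconnections. Stereo and isotope annotations are ignored. Implicit
#' hydrogens on organic-subset atoms follow the standard valence-filling
#' rule, with aromatic bonds counting 1.5 toward the bond-order sum.
#'
#' @param smiles the SMILES string.
#' @param id identifier for the resulting record (default the string itself).
#' @return a [molecule_record()].
#' @export
parse_smiles <- function(smiles, id = smiles) {
  s <- trimws(smiles)
  if (nchar(s) == 0) stop("empty SMILES")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  sym <- character(0); chg <- integer(0); aro <- logical(0); nH <- integer(0)
  explicitH <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bord <- numeric(0)
  prev <- NA_integer_
  pending <- NA_character_
  branch <- integer(0)
  ring <- list()  # closure id -> list(atom, bondsym)

  add_atom <- function(symbol, aromatic, charge, h, h_explicit) {
    sym[length(sym) + 1L] <<- symbol
    aro[length(aro) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    nH[length(nH) + 1L] <<- h
    explicitH[length(explicitH) + 1L] <<- h_explicit
    idx <- length(sym)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- NA_character_
    prev <<- idx
    idx
  }
  add_bond <- function(a, b, bondsym) {
    ord <- if (is.na(bondsym)) {
      if (aro[a] && aro[b]) 1.5 else 1
    } else switch(bondsym,
      "-" = 1, "/" = 1, "\\" = 1, "=" = 2, "#" = 3, ":" = 1.5,
      stop("unsupported bond symbol '", bondsym, "'"))
    b1[length(b1) + 1L] <<- a
    b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- ord
  }
  close_or_open_ring <- function(key) {
    if (is.na(prev)) stop("ring closure before any atom")
    if (!is.null(ring[[key]])) {
      open <- ring[[key]]
      bondsym <- if (!is.na(pending)) pending else open$bondsym
      if (open$atom == prev) stop("ring closure bonds an atom to itself")
      add_bond(open$atom, prev, bondsym)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <<- list(atom = prev, bondsym = pending)
    }
    pending <<- NA_character_
  }

  organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom")
      body <- substr(s, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Za-z][a-z]?)(@@|@)?(H([0-9]*))?(\\+[0-9]+|-[0-9]+|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0) stop("cannot parse bracket atom [", body, "]")
      raw_sym <- m[3]
      aromatic <- substr(raw_sym, 1, 1) %in% letters
      symbol <- paste0(toupper(substr(raw_sym, 1, 1)),
                       substring(raw_sym, 2))
      h <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
      charge <- 0L
      if (m[7] != "") {
        cg <- m[7]
        charge <- if (grepl("^[+-][0-9]+$", cg)) {
          as.integer(cg)
        } else {
          nchar(cg) * (if (substr(cg, 1, 1) == "+") 1L else -1L)
        }
      }
      add_atom(symbol, aromatic, charge, h, h_explicit = TRUE)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, NA_integer_, FALSE)
      i <- i + 2L
    } else if (ch %in% organic) {
      add_atom(ch, FALSE, 0L, NA_integer_, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (ch %in% as.character(1:9) || ch == "0") {
      close_or_open_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure")
      close_or_open_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch with no preceding atom")
      branch <- c(branch, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch) == 0) stop("unbalanced ')'")
      prev <- branch[length(branch)]
      branch <- branch[-length(branch)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_character_
      i <- i + 1L
    } else {
      stop("unsupported SMILES token '", ch, "' in '", s, "'")
    }
  }
  if (length(branch) > 0) stop("unbalanced '(' in '", s, "'")
  if (length(ring) > 0) stop("unclosed ring bond(s) in '", s, "'")
  if (length(sym) == 0) stop("no atoms parsed from '", s, "'")

  # implicit hydrogens for organic-subset atoms
  for (a in seq_along(sym)) {
    if (!explicitH[a]) {
      bs <- sum(bord[b1 == a | b2 == a])
      nH[a] <- .implicit_h(sym[a], chg[a], bs)
    }
  }
  molecule_record(
    id = id,
    atoms = data.frame(symbol = sym, charge = chg, aromatic = aro, nH = nH,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord)
  )
}

#' Read a SMILES file
#'
#' One molecule per line; an optional second whitespace-separated token is
#' taken as the identifier. Unparseable lines are skipped with a warning; the
#' number skipped is attached as attribute `"n_skipped"`.
#'
#' @param path path to the file.
#' @return list of [molecule_record()] objects, in file order.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  mols <- list()
  skipped <- 0L
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]]
    id <- if (length(tok) >= 2) tok[2] else sprintf("SMI%05d", k)
    rec <- tryCatch(parse_smiles(tok[1], id = id), error = function(e) {
      warning("skipping SMILES line ", k, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(rec)) { skipped <- skipped + 1L; next }
    rec$source_index <- k
    mols[[length(mols) + 1L]] <- rec
  }
  if (length(mols) == 0) stop("no parseable molecules in ", path)
  attr(mols, "n_skipped") <- skipped
  mols
}

# ---------------------------------------------------------------------------
# SDF (MDL V2000)

# Map an SD-tag value to an activity label. Documented rule: case-insensitive
# "active"/"1"/"true" -> active; "inactive"/"0"/"false" -> inactive; anything
# else (e.g. "Inconclusive") is unmappable -> the record is dropped upstream.
.map_activity <- function(value) {
  v <- tolower(trimws(value))
  if (v %in% c("active", "1", "true")) "active"
  else if (v %in% c("inactive", "0", "false")) "inactive"
  else NA_character_
}

.parse_sdf_block <- function(lines, block_index) {
  if (length(lines) < 4) stop("molecule block too short")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    tok <- strsplit(trimws(counts), "[[:space:]]+")[[1]]
    natoms <- suppressWarnings(as.integer(tok[1]))
    nbonds <- suppressWarnings(as.integer(tok[2]))
  }
  if (is.na(natoms) || natoms < 1) stop("bad counts line")
  if (length(lines) < 4 + natoms + nbonds) stop("truncated atom/bond block")

  sym <- character(natoms); chg <- integer(natoms)
  for (a in seq_len(natoms)) {
    al <- lines[4 + a]
    symbol <- trimws(substr(al, 32, 34))
    if (symbol == "") {
      tok <- strsplit(trimws(al), "[[:space:]]+")[[1]]
      if (length(tok) < 4) stop("bad atom line ", a)
      symbol <- tok[4]
    }
    sym[a] <- symbol
    code <- suppressWarnings(as.integer(substr(al, 37, 39)))
    chg[a] <- if (!is.na(code) && code %in% 1:7) {
      c(3L, 2L, 1L, 0L, -1L, -2L, -3L)[code]
    } else 0L
  }
  b1 <- integer(nbonds); b2 <- integer(nbonds); bord <- numeric(nbonds)
  for (b in seq_len(nbonds)) {
    bl <- lines[4 + natoms + b]
    a1 <- suppressWarnings(as.integer(substr(bl, 1, 3)))
    a2 <- suppressWarnings(as.integer(substr(bl, 4, 6)))
    oc <- suppressWarnings(as.integer(substr(bl, 7, 9)))
    if (is.na(a1) || is.na(a2) || is.na(oc)) {
      tok <- strsplit(trimws(bl), "[[:space:]]+")[[1]]
      if (length(tok) < 3) stop("bad bond line ", b)
      a1 <- as.integer(tok[1]); a2 <- as.integer(tok[2])
      oc <- as.integer(tok[3])
    }
    if (a1 < 1 || a1 > natoms || a2 < 1 || a2 > natoms || a1 == a2) {
      stop("bond ", b, " references invalid atoms")
    }
    b1[b] <- a1; b2[b] <- a2
    bord[b] <- if (oc == 4) 1.5 else if (oc %in% 1:3) oc else
      stop("unsupported bond order code ", oc)
  }

  rest <- lines[-seq_len(4 + natoms + nbonds)]
  # property block: M CHG overrides the atom-line charge codes
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines) > 0) {
    chg[] <- 0L
    for (cl in chg_lines) {
      tok <- strsplit(trimws(cl), "[[:space:]]+")[[1]]
      k <- as.integer(tok[3])
      for (e in seq_len(k)) {
        chg[as.integer(tok[2 + 2 * e])] <- as.integer(tok[3 + 2 * e])
      }
    }
  }
  # SD data fields
  tags <- list()
  ti <- grep("^>", rest)
  for (t in ti) {
    name <- sub("^>.*<([^>]+)>.*$", "\\1", rest[t])
    val <- if (t + 1 <= length(rest)) trimws(rest[t + 1]) else ""
    tags[[name]] <- val
  }

  aromatic <- logical(natoms)
  for (b in seq_len(nbonds)) {
    if (bord[b] == 1.5) aromatic[c(b1[b], b2[b])] <- TRUE
  }
  # fold explicit hydrogens into the heavy-atom nH counts
  nH <- integer(natoms)
  is_h <- sym == "H"
  if (any(is_h)) {
    for (b in seq_len(nbonds)) {
      if (is_h[b1[b]] && !is_h[b2[b]]) nH[b2[b]] <- nH[b2[b]] + 1L
      if (is_h[b2[b]] && !is_h[b1[b]]) nH[b1[b]] <- nH[b1[b]] + 1L
    }
  }
  for (a in which(!is_h)) {
    bs <- sum(bord[b1 == a | b2 == a])
    nH[a] <- nH[a] + .implicit_h(sym[a], chg[a], bs)
  }
  if (any(is_h)) {  # drop explicit hydrogens, remap indices
    keep <- which(!is_h)
    remap <- integer(natoms); remap[keep] <- seq_along(keep)
    hb <- is_h[b1] | is_h[b2]
    b1 <- remap[b1[!hb]]; b2 <- remap[b2[!hb]]; bord <- bord[!hb]
    sym <- sym[keep]; chg <- chg[keep]; nH <- nH[keep]
    aromatic <- aromatic[keep]
    if (length(sym) == 0) stop("molecule contains only hydrogens")
  }
  # validate elements now so corrupt blocks are caught at parse time
  .elem_prop(sym, "mass")

  name <- trimws(lines[1])
  id <- if (nzchar(name)) name else sprintf("MOL%05d", block_index)
  list(record = molecule_record(
         id = id,
         atoms = data.frame(symbol = sym, charge = chg, aromatic = aromatic,
                            nH = nH, stringsAsFactors = FALSE),
         bonds = data.frame(a1 = b1, a2 = b2, order = bord),
         source_index = block_index),
       tags = tags)
}

#' Read an SDF file
#'
#' Parses MDL V2000 molecule blocks in file order. Malformed blocks are
#' skipped with a warning and counted in attribute `"n_skipped"`. When
#' `activity_tag` is given, its value is mapped case-insensitively
#' ("active"/"1"/"true" vs "inactive"/"0"/"false"); records whose tag value
#' is present but unmappable (e.g. "Inconclusive") are dropped with a
#' warning, so that ambiguous outcomes never enter a training set. Records
#' without the tag are kept unlabelled.
#'
#' @param path path to the .sdf file.
#' @param activity_tag optional SD tag name carrying the activity outcome,
#'   e.g. `"PUBCHEM_ACTIVITY_OUTCOME"`.
#' @return list of [molecule_record()] objects.
#' @export
read_sdf <- function(path, activity_tag = NULL) {
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0 && length(lines) > 0) ends <- length(lines) + 1L
  mols <- list()
  skipped <- 0L
  start <- 1L
  for (k in seq_along(ends)) {
    block <- lines[start:(ends[k] - 1L)]
    start <- ends[k] + 1L
    first <- which(nzchar(trimws(block)))[1]
    if (is.na(first)) next
    block <- block[first:length(block)]
    parsed <- tryCatch(.parse_sdf_block(block, k), error = function(e) {
      warning("skipping SDF block ", k, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(parsed)) { skipped <- skipped + 1L; next }
    rec <- parsed$record
    if (!is.null(activity_tag) && !is.null(parsed$tags[[activity_tag]])) {
      lab <- .map_activity(parsed$tags[[activity_tag]])
      if (is.na(lab)) {
        warning("dropping molecule '", rec$id, "': unmappable ",
                activity_tag, " value '", parsed$tags[[activity_tag]], "'",
                call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      rec$activity <- lab
    }
    mols[[length(mols) + 1L]] <- rec
  }
  if (length(mols) == 0) stop("no parseable molecules in ", path)
  attr(mols, "n_skipped") <- skipped
  mols
}

#' Write molecule records to an SDF file
#'
#' Emits V2000 blocks with zeroed coordinates (the package is 2D/topological
#' throughout), aromatic bonds as order code 4, formal charges as `M  CHG`
#' lines, and explicit hydrogen atoms wherever the implicit-valence rule
#' would not recover the stored hydrogen count (e.g. pyrrole N-H). Activity
#' labels, when present, are written under `activity_tag`.
#'
#' @param mols list of [molecule_record()] objects.
#' @param path output path.
#' @param activity_tag SD tag name used for activity labels.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, activity_tag = "ACTIVITY") {
  out <- character(0)
  for (mol in mols) {
    at <- mol$atoms; bd <- mol$bonds
    na0 <- nrow(at)
    # explicit hydrogens where valence filling would be wrong
    exH <- integer(0)  # heavy-atom index per extra H
    for (a in seq_len(na0)) {
      bs <- if (nrow(bd) > 0) sum(bd$order[bd$a1 == a | bd$a2 == a]) else 0
      if (.implicit_h(at$symbol[a], at$charge[a], bs) != at$nH[a]) {
        exH <- c(exH, rep(a, at$nH[a]))
      }
    }
    natoms <- na0 + length(exH)
    nbonds <- nrow(bd) + length(exH)
    blk <- c(mol$id, "  rfscreen 2D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     natoms, nbonds))
    for (a in seq_len(na0)) {
      blk <- c(blk, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        0, 0, 0, at$symbol[a]))
    }
    for (h in exH) {
      blk <- c(blk, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        0, 0, 0, "H"))
    }
    if (nrow(bd) > 0) {
      for (b in seq_len(nrow(bd))) {
        code <- if (bd$order[b] == 1.5) 4L else as.integer(bd$order[b])
        blk <- c(blk, sprintf("%3d%3d%3d  0", bd$a1[b], bd$a2[b], code))
      }
    }
    for (h in seq_along(exH)) {
      blk <- c(blk, sprintf("%3d%3d%3d  0", exH[h], na0 + h, 1L))
    }
    charged <- which(at$charge != 0)
    if (length(charged) > 0) {
      blk <- c(blk, paste0("M  CHG", sprintf("%3d", length(charged)),
                           paste0(sprintf("%4d%4d", charged,
                                          at$charge[charged]),
                                  collapse = "")))
    }
    blk <- c(blk, "M  END")
    if (!is.na(mol$activity)) {
      blk <- c(blk, sprintf(">  <%s>", activity_tag),
               if (mol$activity == "active") "Active" else "Inactive", "")
    }
    blk <- c(blk, "$$$$")
    out <- c(out, blk)
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
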