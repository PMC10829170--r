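# SMILES parsing, canonicalization, randomized enumeration, Murcko scaffolds,
# circular fingerprints and molecule/pair table I/O. All chemistry goes
# through OpenBabel (ChemmineOB); molecular graphs are handled as V2000 MOL
# blocks so atom order can be permuted and substructures re-emitted.

ob_convert <- function(from, to, source) {
  ChemmineOB::convertFormat(from, to, source,
                            options = data.frame(names = character(),
                                                 args = character()))
}

# OpenBabel silently repairs unmatched parentheses/brackets instead of
# failing, so syntactic balance is checked here before handing over.
smiles_balanced <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth_p <- 0L; depth_b <- 0L
  for (ch in chars) {
    if (ch == "(") depth_p <- depth_p + 1L
    else if (ch == ")") depth_p <- depth_p - 1L
    else if (ch == "[") depth_b <- depth_b + 1L
    else if (ch == "]") depth_b <- depth_b - 1L
    if (depth_p < 0L || depth_b < 0L) return(FALSE)
  }
  depth_p == 0L && depth_b == 0L
}

strip_title <- function(lines) sub("[ \t].*$", "", lines)

# Batch canonicalization. OpenBabel aborts a multi-molecule conversion at the
# first invalid record, so the batch is restarted after each failure; row
# identity is tracked through the SMILES title field. Returns NA for rows
# that fail.
canonicalize_batch <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[ \t]", smiles) &
    vapply(ifelse(is.na(smiles), "", smiles), smiles_balanced, TRUE)
  todo <- which(ok)
  while (length(todo) > 0L) {
    src <- paste(smiles[todo], todo, collapse = "\n")
    res <- ob_convert("SMI", "CAN", src)
    lines <- strsplit(res, "\n")[[1]]
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "\t")[[1]]
      if (length(parts) >= 2L) out[as.integer(parts[2])] <- parts[1]
    }
    n_got <- length(lines)
    if (n_got >= length(todo)) break
    todo <- todo[-seq_len(n_got + 1L)]  # skip the record that failed
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Maps every valid encoding of a molecule to the unique canonical SMILES
#' assigned by OpenBabel, the equivalence oracle used throughout the package
#' (two SMILES denote the same molecule iff they canonicalize identically).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \donttest{
#' canonicalize(c("OCC", "CCO"))  # both "CCO"
#' }
#' @export
canonicalize <- function(smiles) {
  if (length(smiles) == 0L) return(character())
  if (!is.character(smiles)) parse_error(smiles, "not a character vector")
  out <- canonicalize_batch(smiles)
  if (anyNA(out)) parse_error(smiles[which(is.na(out))[1]])
  out
}

# ---- MOL block handling -----------------------------------------------------

parse_molblock <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  natoms <- as.integer(substr(lines[4], 1, 3))
  nbonds <- as.integer(substr(lines[4], 4, 6))
  atom_lines <- if (natoms > 0L) lines[5:(4L + natoms)] else character()
  bond_lines <- if (nbonds > 0L) lines[(5L + natoms):(4L + natoms + nbonds)] else character()
  bonds <- if (nbonds > 0L) {
    t(vapply(bond_lines, function(s) {
      c(as.integer(substr(s, 1, 3)), as.integer(substr(s, 4, 6)),
        as.integer(substr(s, 7, 9)))
    }, integer(3), USE.NAMES = FALSE))
  } else matrix(integer(), 0, 3)
  chg <- matrix(integer(), 0, 2)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    n <- tok[1]
    pairs <- matrix(tok[-1], ncol = 2, byrow = TRUE)[seq_len(n), , drop = FALSE]
    chg <- rbind(chg, pairs)
  }
  list(natoms = natoms, atom_lines = atom_lines, bonds = bonds, chg = chg)
}

# Re-emit a MOL block with atoms reordered by `perm` (perm[k] = original index
# of the atom placed at position k) and optionally restricted to `keep`
# (original indices). Bond and charge tables are remapped accordingly.
write_molblock <- function(g, perm = seq_len(g$natoms), keep = NULL) {
  if (!is.null(keep)) perm <- perm[perm %in% keep]
  inv <- integer(g$natoms)
  inv[perm] <- seq_along(perm)
  b <- g$bonds
  if (nrow(b) > 0L) {
    sel <- inv[b[, 1]] > 0L & inv[b[, 2]] > 0L
    b <- b[sel, , drop = FALSE]
    b[, 1] <- inv[b[, 1]]; b[, 2] <- inv[b[, 2]]
  }
  chg_lines <- character()
  if (nrow(g$chg) > 0L) {
    sel <- inv[g$chg[, 1]] > 0L
    if (any(sel)) {
      pairs <- g$chg[sel, , drop = FALSE]
      chg_lines <- sprintf("M  CHG%3d%s", nrow(pairs),
                           paste0(sprintf("%4d%4d", inv[pairs[, 1]], pairs[, 2]),
                                  collapse = ""))
    }
  }
  paste(c("", " contrastDDI", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(perm), nrow(b)),
          g$atom_lines[perm],
          if (nrow(b) > 0L) sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], b[, 3]),
          chg_lines,
          "M  END", "$$$$", ""), collapse = "\n")
}

mol_graph <- function(smiles) {
  canonicalize(smiles)  # validity gate
  parse_molblock(ob_convert("SMI", "SDF", smiles))
}

#' Enumerate randomized SMILES views of a molecule
#'
#' Produces alternative valid SMILES spellings of the same molecule by
#' permuting the atom order of its molfile representation with a seeded RNG
#' and re-emitting a (non-canonical) SMILES, mirroring the molfile round-trip
#' used for SMILES-enumeration data augmentation. At most `cap` distinct
#' views are returned (default 50); molecules with few atoms may admit fewer.
#'
#' @param smiles a single valid SMILES string.
#' @param n_requested maximum number of views wanted (>= 1).
#' @param seed integer seed; the view set is reproducible under it.
#' @param cap hard upper bound on the number of views (default 50,
#'   overridable globally via `options(contrastDDI.view_cap = )`).
#' @return character vector of 1..min(n_requested, cap) distinct SMILES, each
#'   canonicalizing back to `canonicalize(smiles)`.
#' @export
enumerate_randomized <- function(smiles, n_requested, seed = 0L,
                                 cap = getOption("contrastDDI.view_cap", 50L)) {
  if (length(smiles) != 1L) parse_error(smiles, "expected a single string")
  if (n_requested < 1L) value_error("n_requested must be >= 1")
  g <- mol_graph(smiles)
  n_target <- min(as.integer(n_requested), as.integer(cap))
  views <- character()
  with_seed(seed, {
    attempts <- 0L
    max_attempts <- max(20L, 6L * n_target)
    while (length(views) < n_target && attempts < max_attempts) {
      batch_n <- min(max(n_target - length(views), 1L) + 4L, 32L)
      perms <- replicate(batch_n, sample.int(g$natoms), simplify = FALSE)
      blocks <- vapply(perms, function(p) write_molblock(g, p), character(1))
      res <- ob_convert("MOL", "SMI", paste(blocks, collapse = ""))
      smis <- strip_title(strsplit(res, "\n", fixed = TRUE)[[1]])
      views <- unique(c(views, smis[nzchar(smis)]))
      attempts <- attempts + batch_n
    }
  })
  utils::head(views, n_target)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Returns the canonical SMILES of the molecule's scaffold: all ring systems
#' plus the linker atoms connecting them, with side chains removed. Atoms
#' attached to the scaffold by a double or triple bond (e.g. exocyclic
#' carbonyl oxygens) are retained. Acyclic molecules have no scaffold and
#' yield the empty string; they form their own "no-scaffold" family in
#' downstream analyses.
#'
#' @param smiles a single valid SMILES string.
#' @return canonical scaffold SMILES, or `""` for acyclic molecules.
#' @export
murcko_scaffold <- function(smiles) {
  if (length(smiles) != 1L) parse_error(smiles, "expected a single string")
  g <- mol_graph(smiles)
  if (g$natoms == 0L || nrow(g$bonds) == 0L) return("")
  # 2-core of the bond graph: iteratively strip terminal atoms. What remains
  # is exactly rings + inter-ring linkers.
  keep <- rep(TRUE, g$natoms)
  repeat {
    deg <- integer(g$natoms)
    b <- g$bonds[keep[g$bonds[, 1]] & keep[g$bonds[, 2]], , drop = FALSE]
    if (nrow(b) > 0L) {
      tab <- table(factor(c(b[, 1], b[, 2]), levels = seq_len(g$natoms)))
      deg <- as.integer(tab)
    }
    terminal <- keep & deg <= 1L
    if (!any(terminal)) break
    keep[terminal] <- FALSE
  }
  if (!any(keep)) return("")
  # retain atoms multiple-bonded to the core (exocyclic =O, =N, etc.)
  core <- which(keep)
  multi <- g$bonds[, 3] >= 2L
  extra <- c(g$bonds[multi & g$bonds[, 1] %in% core, 2],
             g$bonds[multi & g$bonds[, 2] %in% core, 1])
  keep_idx <- sort(unique(c(core, extra)))
  block <- write_molblock(g, keep = keep_idx)
  out <- strip_title(ob_convert("MOL", "CAN", block))
  sub("\n$", "", out)
}

# ---- fingerprints -----------------------------------------------------------

#' Hashed circular (ECFP) fingerprint
#'
#' Extended-connectivity fingerprint computed by OpenBabel (`ECFP{2*radius}`,
#' a 4096-bit hashed set) and folded by index modulo to the requested width.
#'
#' @param smiles a single valid SMILES string.
#' @param radius neighborhood radius (0..5); the conventional "ECFP4" is
#'   `radius = 2`.
#' @param n_bits folded fingerprint length (default 2048).
#' @return object of class `fingerprint`: list with `bits` (0/1 integer
#'   vector of length `n_bits`), `n_bits`, `radius`.
#' @export
circular_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  if (radius < 0L || radius > 5L) value_error("radius must be in 0..5")
  if (n_bits < 1L) value_error("n_bits must be >= 1")
  canonicalize(smiles)
  mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  raw <- as.integer(as.numeric(
    ChemmineOB::fingerprint_OB(mols, sprintf("ECFP%d", 2L * as.integer(radius)))))
  on <- which(raw != 0L) - 1L
  bits <- integer(n_bits)
  bits[(on %% n_bits) + 1L] <- 1L
  structure(list(bits = bits, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d/%d bits set, radius %d>\n",
              sum(x$bits), x$n_bits, x$radius))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' @param a,b `fingerprint` objects (or plain 0/1 vectors) of equal length.
#' @return Tanimoto (Jaccard) similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  va <- if (inherits(a, "fingerprint")) a$bits else as.integer(a)
  vb <- if (inherits(b, "fingerprint")) b$bits else as.integer(b)
  if (length(va) != length(vb)) shape_error("fingerprint lengths differ")
  inter <- sum(va & vb)
  uni <- sum(va | vb)
  if (uni == 0L) degenerate_vector_error("both fingerprints are empty")
  inter / uni
}

# ---- tables -----------------------------------------------------------------

read_delim_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) return(data.frame())
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

#' Build a molecule table from SMILES strings
#'
#' Canonicalizes each SMILES and attaches its Murcko scaffold. Strings that
#' fail to parse are dropped with a warning reporting the count.
#'
#' @param smiles character vector.
#' @param id optional identifiers (defaults to `mol_<row>`).
#' @return data.frame with columns `id`, `smiles_canonical`, `scaffold`.
#' @export
molecule_table <- function(smiles, id = NULL) {
  id <- id %||% sprintf("mol_%d", seq_along(smiles))
  if (length(id) != length(smiles)) shape_error("id and smiles lengths differ")
  canon <- canonicalize_batch(smiles)
  bad <- is.na(canon)
  if (any(bad)) {
    warning(sprintf("skipped %d unparsable SMILES (e.g. %s)",
                    sum(bad), deparse(smiles[which(bad)[1]])))
  }
  canon <- canon[!bad]; id <- id[!bad]
  scaff_map <- new.env(parent = emptyenv())
  scaffold <- vapply(canon, function(s) {
    if (!is.null(scaff_map[[s]])) return(scaff_map[[s]])
    v <- tryCatch(murcko_scaffold(s), error = function(e) "")
    scaff_map[[s]] <- v
    v
  }, character(1), USE.NAMES = FALSE)
  data.frame(id = id, smiles_canonical = canon, scaffold = scaffold,
             stringsAsFactors = FALSE)
}

#' Load a molecule table from disk
#'
#' Reads a CSV/TSV with a named SMILES column, or a `.smi` file (one SMILES
#' per line, optional identifier after whitespace). Rows failing
#' canonicalization are skipped with a warning.
#'
#' @param path file path.
#' @param smiles_column name of the SMILES column (ignored for `.smi`).
#' @param id_column optional name of an identifier column.
#' @return data.frame with columns `id`, `smiles_canonical`, `scaffold`.
#' @export
load_molecule_table <- function(path, smiles_column = "smiles",
                                id_column = NULL) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  if (grepl("\\.smi$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(molecule_table(character()))
    parts <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(parts, `[`, character(1), 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_,
                  character(1))
    if (anyNA(ids)) ids <- NULL
    return(molecule_table(smiles, ids))
  }
  tab <- read_delim_table(path)
  if (nrow(tab) == 0L && ncol(tab) == 0L) return(molecule_table(character()))
  if (!smiles_column %in% names(tab))
    schema_error(sprintf("column %s not present in %s",
                         deparse(smiles_column), path))
  ids <- if (!is.null(id_column)) {
    if (!id_column %in% names(tab))
      schema_error(sprintf("column %s not present in %s",
                           deparse(id_column), path))
    as.character(tab[[id_column]])
  } else NULL
  molecule_table(as.character(tab[[smiles_column]]), ids)
}

#' Write a molecule table as CSV
#' @param molecules data.frame from [molecule_table()].
#' @param path output file.
#' @export
write_molecule_table <- function(molecules, path) {
  utils::write.csv(molecules[, c("id", "smiles_canonical", "scaffold")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Load a DDI pair table
#'
#' Reads a CSV/TSV of drug pairs with a side-effect label column. String
#' labels are mapped to a stable integer code 0..C-1 through a sorted label
#' registry kept in `attr(, "label_levels")`.
#'
#' @param path file path.
#' @param drug1_column,drug2_column,label_column column names.
#' @return data.frame with columns `drug1_smiles`, `drug2_smiles`, `label`
#'   (integer codes) plus the label registry attribute.
#' @export
load_pair_table <- function(path, drug1_column = "drug1_smiles",
                            drug2_column = "drug2_smiles",
                            label_column = "label") {
  tab <- read_delim_table(path)
  need <- c(drug1_column, drug2_column, label_column)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    schema_error(sprintf("missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  labels_raw <- tab[[label_column]]
  levels <- sort(unique(as.character(labels_raw)))
  out <- data.frame(drug1_smiles = as.character(tab[[drug1_column]]),
                    drug2_smiles = as.character(tab[[drug2_column]]),
                    label = match(as.character(labels_raw), levels) - 1L,
                    stringsAsFactors = FALSE)
  attr(out, "label_levels") <- levels
  out
}
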