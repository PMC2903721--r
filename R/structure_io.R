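# PDB-format reading/writing and residue classification.
#
# The container mirrors the file: a molecular structure file holds one or
# more structure models (NMR entries hold several), each model holds chains
# of residues, each residue an atom table. Author numbering (seq_num +
# insertion code) is authoritative throughout and is what appears in minted
# URIs downstream.

#' Construct an atom record
#' @param name PDB atom name, e.g. `"O2'"`.
#' @param position Numeric 3-vector, Angstrom.
#' @param element Element symbol; guessed from the name when empty.
#' @param occupancy Occupancy in `[0, 1]`.
#' @param altloc Alternate-location indicator (single character or `""`).
#' @return A one-row atom data frame.
#' @export
atom_record <- function(name, position, element = "", occupancy = 1,
                        altloc = "") {
  stopifnot(nzchar(name), length(position) == 3, all(is.finite(position)))
  if (!nzchar(element)) element <- guess_element(name)
  data.frame(name = name, element = element,
             x = position[1], y = position[2], z = position[3],
             occupancy = occupancy, altloc = altloc,
             stringsAsFactors = FALSE)
}

#' Construct a residue
#' @param chain_id Chain identifier (single character).
#' @param seq_num Author residue number (integer).
#' @param res_name Residue name, e.g. `"G"`, `"HOH"`.
#' @param atoms Atom data frame (rows as built by [atom_record()]).
#' @param icode Insertion code (`""` when absent).
#' @return A `residue` object; `residue_class` is assigned by
#'   [classify_residue()].
#' @export
new_residue <- function(chain_id, seq_num, res_name, atoms, icode = "") {
  r <- structure(
    list(chain_id = chain_id, seq_num = as.integer(seq_num), icode = icode,
         res_name = res_name, atoms = atoms, residue_class = NA_character_),
    class = "residue"
  )
  r$residue_class <- classify_residue(r)
  r
}

#' @export
print.residue <- function(x, ...) {
  cat(sprintf("<residue %s %s%d%s [%s], %d atoms>\n", x$res_name, x$chain_id,
              x$seq_num, x$icode, x$residue_class, nrow(x$atoms)))
  invisible(x)
}

residue_key <- function(r) {
  paste0(r$chain_id, ":", r$seq_num, r$icode)
}

#' Construct a molecular structure file object
#' @param pdb_id 4-character PDB identifier (stored uppercase).
#' @param models List of structure models, each a list with `model_num` and
#'   `chains` (named list chain_id -> list of residues).
#' @param source_path Origin path, `""` for in-memory structures.
#' @return A `molecular_structure_file` object.
#' @export
new_structure_file <- function(pdb_id, models, source_path = "") {
  stopifnot(length(models) >= 1)
  skel <- lapply(models, model_skeleton)
  for (k in seq_along(skel)[-1]) {
    if (!identical(skel[[k]], skel[[1]])) {
      warning("models do not share the same residue skeleton (model ",
              models[[k]]$model_num, ")")
      break
    }
  }
  structure(
    list(pdb_id = toupper(pdb_id), models = models,
         source_path = source_path),
    class = "molecular_structure_file"
  )
}

#' @export
print.molecular_structure_file <- function(x, ...) {
  nres <- sum(vapply(x$models[[1]]$chains, length, 1L))
  cat(sprintf("<molecular structure file PDB:%s, %d model(s), %d chain(s), %d residues/model>\n",
              x$pdb_id, length(x$models), length(x$models[[1]]$chains), nres))
  invisible(x)
}

model_skeleton <- function(model) {
  lapply(model$chains, function(ch) {
    lapply(ch, function(r) list(r$chain_id, r$seq_num, r$icode, r$res_name))
  })
}

# Residue names accepted as standard ribonucleotides (current + legacy).
STANDARD_RES_NAMES <- c(A = "A", ADE = "A", C = "C", CYT = "C",
                        G = "G", GUA = "G", U = "U", URA = "U")
BASE_RING_NAMES <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")

#' Classify a residue as ribonucleotide, modified nucleotide or other
#'
#' A residue is a standard ribonucleotide (class `A`/`C`/`G`/`U`) when its
#' name is standard (including legacy `ADE`/`CYT`/`GUA`/`URA`), it carries an
#' O2' atom and at least six nucleobase ring atoms. Residues with a
#' nucleobase ring but a nonstandard name (or missing O2') are `modified`;
#' anything else is `non_nucleic`. Classification depends only on atom
#' content, never on ATOM vs HETATM record type.
#'
#' @param r A `residue`.
#' @return One of `"A"`, `"C"`, `"G"`, `"U"`, `"modified"`, `"non_nucleic"`.
#' @export
classify_residue <- function(r) {
  n_ring <- sum(BASE_RING_NAMES %in% r$atoms$name)
  has_o2p <- "O2'" %in% r$atoms$name
  std <- STANDARD_RES_NAMES[toupper(r$res_name)]
  if (!is.na(std) && has_o2p && n_ring >= 6) return(unname(std))
  if (n_ring >= 6) return("modified")
  "non_nucleic"
}

#' Read a PDB-format file
#'
#' Recognizes ATOM/HETATM/MODEL/ENDMDL/TER records (fixed columns); all other
#' records are ignored. A file without MODEL records yields a single model
#' numbered 1. Alternate locations are resolved per residue by keeping the
#' highest-occupancy atom of each name (ties: first in file).
#'
#' @param input Path to a PDB file, or a character vector of lines.
#' @param pdb_id 4-character identifier; defaults to the HEADER id when
#'   present, else the file name stem, else `"XXXX"`.
#' @return A `molecular_structure_file`.
#' @export
read_pdb <- function(input, pdb_id = NULL) {
  src <- ""
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    src <- input
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty PDB input")
  }

  if (is.null(pdb_id)) {
    hdr <- lines[startsWith(lines, "HEADER")]
    if (length(hdr) && nchar(hdr[1]) >= 66) {
      cand <- trimws(substr(hdr[1], 63, 66))
      if (nchar(cand) == 4) pdb_id <- cand
    }
    if (is.null(pdb_id) && nzchar(src)) {
      stem <- sub("\\.[^.]*$", "", basename(src))
      if (nchar(stem) == 4) pdb_id <- stem
    }
    if (is.null(pdb_id)) pdb_id <- "XXXX"
  }

  rec <- substr(lines, 1, 6)
  models <- list()
  cur_num <- NA_integer_
  cur_rows <- list()
  saw_model <- FALSE

  flush_model <- function(num, rows) {
    if (length(rows) == 0) return(NULL)
    build_model(num, do.call(rbind, rows))
  }

  for (i in seq_along(lines)) {
    r6 <- rec[i]
    if (r6 == "MODEL ") {
      saw_model <- TRUE
      if (length(cur_rows)) {
        models[[length(models) + 1]] <- flush_model(cur_num, cur_rows)
        cur_rows <- list()
      }
      cur_num <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 80))))
      if (is.na(cur_num)) stop("malformed MODEL record at line ", i)
    } else if (r6 == "ENDMDL") {
      models[[length(models) + 1]] <- flush_model(cur_num, cur_rows)
      cur_rows <- list()
      cur_num <- NA_integer_
    } else if (r6 == "ATOM  " || r6 == "HETATM") {
      cur_rows[[length(cur_rows) + 1]] <- parse_atom_line(lines[i], i)
    }
    # TER and everything else: no structural content retained
  }
  if (length(cur_rows)) {
    models[[length(models) + 1]] <-
      flush_model(if (saw_model) cur_num else 1L, cur_rows)
  }
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop("no atoms found in PDB input")
  new_structure_file(pdb_id, models, src)
}

parse_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    stop("malformed ATOM/HETATM record (too short) at line ", lineno)
  }
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz)) {
    stop("malformed ATOM/HETATM record (non-numeric coordinates) at line ",
         lineno)
  }
  occ <- suppressWarnings(as.numeric(substr(line, 55, 60)))
  if (is.na(occ)) occ <- 1
  name <- trimws(substr(line, 13, 16))
  if (!nzchar(name)) stop("malformed ATOM/HETATM record (empty atom name) at line ", lineno)
  elem <- trimws(substr(line, 77, 78))
  if (!nzchar(elem)) elem <- guess_element(name)
  data.frame(
    name = name, element = elem, altloc = trimws(substr(line, 17, 17)),
    res_name = trimws(substr(line, 18, 20)),
    chain_id = trimws(substr(line, 22, 22)),
    seq_num = suppressWarnings(as.integer(substr(line, 23, 26))),
    icode = trimws(substr(line, 27, 27)),
    x = xyz[1], y = xyz[2], z = xyz[3], occupancy = occ,
    stringsAsFactors = FALSE
  )
}

guess_element <- function(name) {
  e <- sub("^[0-9']*", "", name)
  substr(e, 1, 1)
}

build_model <- function(model_num, tab) {
  if (anyNA(tab$seq_num)) stop("ATOM record with non-numeric residue number")
  chains <- list()
  for (ck in unique(tab$chain_id)) {
    sub <- tab[tab$chain_id == ck, , drop = FALSE]
    ukey <- !duplicated(paste(sub$seq_num, sub$icode, sep = "\r"))
    useq <- sub$seq_num[ukey]
    uic <- sub$icode[ukey]
    # order by author numbering (seq_num, icode)
    ord <- order(useq, uic)
    rkeys <- paste(useq, uic, sep = "\r")[ord]
    residues <- list()
    for (rk in rkeys) {
      rsub <- sub[paste(sub$seq_num, sub$icode, sep = "\r") == rk, ,
                  drop = FALSE]
      rsub <- resolve_altloc(rsub)
      atoms <- rsub[, c("name", "element", "x", "y", "z", "occupancy",
                        "altloc")]
      rownames(atoms) <- NULL
      residues[[length(residues) + 1]] <-
        new_residue(ck, rsub$seq_num[1], rsub$res_name[1], atoms,
                    rsub$icode[1])
    }
    chains[[ck]] <- residues
  }
  list(model_num = as.integer(model_num), chains = chains)
}

# Keep, for each atom name, the highest-occupancy alternate (ties: first).
resolve_altloc <- function(rows) {
  if (all(!nzchar(rows$altloc))) return(rows)
  keep <- unlist(lapply(split(seq_len(nrow(rows)), rows$name), function(idx) {
    idx[which.max(rows$occupancy[idx])]
  }), use.names = FALSE)
  rows[sort(keep), , drop = FALSE]
}

#' Write a structure to PDB format
#'
#' Coordinates are written to three decimals in columns 31-54. Multi-model
#' files are framed with MODEL/ENDMDL; single-model files omit the framing
#' unless `single_model_writes_model_record = TRUE`.
#'
#' @param f A `molecular_structure_file`.
#' @param path Optional output path; when `NULL` the text is returned.
#' @param single_model_writes_model_record Write MODEL/ENDMDL even for a
#'   one-model file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_pdb <- function(f, path = NULL, single_model_writes_model_record = FALSE) {
  stopifnot(inherits(f, "molecular_structure_file"))
  if (length(f$models) == 0) stop("structure has no models")
  frame <- length(f$models) > 1 || single_model_writes_model_record
  out <- character(0)
  for (m in f$models) {
    if (frame) out <- c(out, sprintf("MODEL     %4d", m$model_num))
    serial <- 0L
    for (ck in names(m$chains)) {
      if (nchar(ck) > 1) stop("chain id '", ck, "' exceeds the 1-character PDB column")
      for (r in m$chains[[ck]]) {
        for (i in seq_len(nrow(r$atoms))) {
          a <- r$atoms[i, ]
          if (!all(is.finite(c(a$x, a$y, a$z)))) {
            stop("non-finite coordinates for atom ", a$name, " in residue ",
                 residue_key(r))
          }
          serial <- serial + 1L
          nm <- a$name
          nm <- if (nchar(nm) >= 4) substr(nm, 1, 4) else
            sprintf(" %-3s", nm)
          out <- c(out, sprintf(
            "ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial %% 100000L, nm, substr(paste0(a$altloc, " "), 1, 1),
            r$res_name, ck, r$seq_num, substr(paste0(r$icode, " "), 1, 1),
            a$x, a$y, a$z, a$occupancy, 0, a$element))
        }
      }
      out <- c(out, "TER")
    }
    if (frame) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
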