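# Structure input/output and the protocol's input dialects.

.residueKey <- function(chain, resno, icode = "") {
  paste0(chain, resno, gsub(" ", "", icode))
}

# Build a validated ProteinStructure from an atom table. Residues missing
# any of N/CA/C are dropped with a warning; chi1 is measured from the
# gamma atom when present, else defaults to trans (180) for rotameric
# types and NA for ALA/GLY.
.structureFromAtoms <- function(atoms, source = "<memory>", model = 1) {
  atoms$icode[is.na(atoms$icode)] <- ""
  bad <- !(atoms$resid %in% names(AA_ONE))
  if (any(bad)) {
    stop("unknown residue name: ", paste(unique(atoms$resid[bad]),
                                         collapse = ", "))
  }
  akey <- .residueKey(atoms$chain, atoms$resno, atoms$icode)
  keys <- unique(akey)
  keep <- logical(length(keys))
  for (i in seq_along(keys)) {
    names_i <- atoms$elety[akey == keys[i]]
    keep[i] <- all(c("N", "CA", "C") %in% names_i)
  }
  if (any(!keep)) {
    warning("dropping residue(s) with incomplete backbone: ",
            paste(keys[!keep], collapse = ", "))
  }
  keys <- keys[keep]
  if (length(keys) == 0) stop("no protein residues with complete backbone")
  atoms <- atoms[akey %in% keys, , drop = FALSE]
  akey <- .residueKey(atoms$chain, atoms$resno, atoms$icode)

  first <- match(keys, akey)
  res <- data.frame(
    key = keys,
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    icode = atoms$icode[first],
    aa = unname(AA_ONE[atoms$resid[first]]),
    chi1 = NA_real_,
    stringsAsFactors = FALSE)

  for (i in seq_len(nrow(res))) {
    if (res$aa[i] %in% c("A", "G")) next
    sub <- atoms[akey == res$key[i], , drop = FALSE]
    g <- sub[sub$elety %in% GAMMA_ATOMS, , drop = FALSE]
    if (nrow(g) >= 1 && "CB" %in% sub$elety) {
      xyz <- function(nm) as.numeric(sub[match(nm, sub$elety),
                                         c("x", "y", "z")])
      res$chi1[i] <- dihedralAngle(xyz("N"), xyz("CA"), xyz("CB"),
                                   as.numeric(g[1, c("x", "y", "z")]))
    } else {
      res$chi1[i] <- 180
    }
  }
  rownames(atoms) <- NULL
  methods::new("ProteinStructure", atoms = atoms, residues = res,
               provenance = list(source = source, model = model))
}

#' Read a protein structure from a PDB file
#'
#' Reads one model of a PDB file into a \linkS4class{ProteinStructure}.
#' HETATM records (waters, ligands) are dropped; alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' letter); residues missing any of the N, CA, C backbone atoms are
#' rejected with a warning.
#'
#' @param path path to a PDB file with at least one ATOM record.
#' @param model model number to extract (1-based; NMR files contain
#'   several).
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDB(makeToyStructure(toySpec(8)), pdb)
#' s <- readPDB(pdb)
#' nResidues(s)
#' @export
readPDB <- function(path, model = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model) {
      stop("model ", model, " not present in ", path)
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    prot <- pdb$atom$type == "ATOM"
    at[, c("x", "y", "z")] <- xyz[prot, , drop = FALSE]
  }
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep, per residue/atom name, the highest-occupancy conformer
  # (ties broken by altloc letter, 'A' first).
  if (any(at$alt != "")) {
    id <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(id, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  atoms <- data.frame(elety = at$elety, x = at$x, y = at$y, z = at$z,
                      chain = at$chain, resno = at$resno, icode = at$insert,
                      resid = at$resid, occ = at$o, stringsAsFactors = FALSE)
  .structureFromAtoms(atoms, source = basename(path), model = model)
}

#' Write a ProteinStructure to a PDB file
#'
#' Writes the atom table back out as ATOM records (3-decimal coordinates),
#' so read/write round trips preserve residue count, sequence and
#' coordinates.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePDB <- function(s, path) {
  at <- s@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(at$icode == "", NA, at$icode),
                   elety = at$elety, o = at$occ, b = rep(0, nrow(at)),
                   eleno = seq_len(nrow(at)))
  invisible(path)
}

#' Parse a resfile into a DesignSpec
#'
#' The resfile dialect: an optional default command line, a `start`
#' separator, then per-residue lines `resnum chain COMMAND [letters]`.
#' Commands: `ALLAA` (design, all 20 types), `PIKAA XYZ` (design, listed
#' types), `NATAA` (repack only), `NATRO` (fixed). The default command is
#' applied to every residue not listed after `start`.
#'
#' @param text resfile content as a single string or character vector of
#'   lines.
#' @param s the \linkS4class{ProteinStructure} the resfile refers to.
#' @return a \linkS4class{DesignSpec}.
#' @examples
#' s <- makeToyStructure(toySpec(5))
#' parseResfile("NATAA\nstart\n2 A PIKAA ACD", s)
#' @export
parseResfile <- function(text, s) {
  lines <- if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  lines <- sub("#.*", "", lines)
  trimmed <- trimws(lines)
  startAt <- which(tolower(trimmed) == "start")
  if (length(startAt) == 0) stop("resfile lacks a 'start' separator")
  startAt <- startAt[1]
  header <- trimmed[seq_len(startAt - 1)]
  header <- header[nzchar(header)]
  default <- if (length(header)) toupper(header[length(header)]) else "NATAA"
  default <- strsplit(default, "\\s+")[[1]][1]
  cmds <- c("ALLAA", "PIKAA", "NATAA", "NATRO")
  if (!default %in% c("NATAA", "NATRO", "ALLAA")) {
    stop("unsupported default resfile command: ", default)
  }

  keys <- residueKeys(s)
  designed <- list()
  repacked <- character()
  nonmoving <- character()
  listed <- character()

  body <- seq(startAt + 1, length.out = max(0, length(trimmed) - startAt))
  for (ln in body) {
    line <- trimmed[ln]
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) < 3) stop("malformed resfile line ", ln, ": ", line)
    key <- .residueKey(tok[2], tok[1])
    if (!key %in% keys) stop("resfile line ", ln, ": residue ", key,
                             " not in structure")
    cmd <- toupper(tok[3])
    if (!cmd %in% cmds) stop("resfile line ", ln,
                             ": unknown command ", tok[3])
    listed <- c(listed, key)
    if (cmd == "ALLAA") {
      designed[[key]] <- AA_ALPHABET
    } else if (cmd == "PIKAA") {
      if (length(tok) < 4) stop("resfile line ", ln, ": PIKAA needs letters")
      letters <- strsplit(toupper(tok[4]), "")[[1]]
      if (!all(letters %in% AA_ALPHABET)) {
        stop("resfile line ", ln, ": invalid PIKAA letter(s) ",
             paste(setdiff(letters, AA_ALPHABET), collapse = ""))
      }
      designed[[key]] <- unique(letters)
    } else if (cmd == "NATAA") {
      repacked <- c(repacked, key)
    } else {
      nonmoving <- c(nonmoving, key)
    }
  }

  rest <- setdiff(keys, listed)
  if (default == "NATAA") repacked <- c(repacked, rest)
  if (default == "NATRO") nonmoving <- c(nonmoving, rest)
  if (default == "ALLAA") for (k in rest) designed[[k]] <- AA_ALPHABET

  methods::new("DesignSpec", premutated = stats::setNames(character(), character()),
               designed = designed, repacked = repacked,
               nonmoving = nonmoving)
}

#' Select the repack shell around designed positions
#'
#' Returns every position whose CA atom lies within `radius` of the CA of
#' any designed position (boundary inclusive). The designed positions are
#' always included since their self-distance is zero.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param designed character vector of designed position keys.
#' @param radius shell radius in Angstrom (default 10).
#' @return character vector of position keys.
#' @export
autoRepackShell <- function(s, designed, radius = 10) {
  stopifnot(length(designed) > 0, radius > 0)
  ca <- caCoords(s)
  if (!all(designed %in% rownames(ca))) {
    stop("designed position lacking CA: ",
         paste(setdiff(designed, rownames(ca)), collapse = ", "))
  }
  d <- ca[designed, , drop = FALSE]
  inShell <- rep(FALSE, nrow(ca))
  for (i in seq_len(nrow(d))) {
    dist <- sqrt(rowSums(sweep(ca, 2, d[i, ])^2))
    inShell <- inShell | dist <= radius
  }
  rownames(ca)[inShell]
}

#' Parse a movemap into a MoveMap
#'
#' Line dialect: `RESIDUE <key|*> CHI|BBCHI|NO` sets per-position chi /
#' chi+backbone / no movable torsions; `JUMP <chain|*> YES|NO` sets the
#' per-chain rigid-body flag. Unlisted positions are immovable. A bare
#' residue number is accepted when the structure has a single chain.
#'
#' @param text movemap content (string or lines).
#' @param s the \linkS4class{ProteinStructure} it refers to.
#' @return a \linkS4class{MoveMap}.
#' @export
parseMovemap <- function(text, s) {
  lines <- if (length(text) == 1) strsplit(text, "\n")[[1]] else text
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  keys <- residueKeys(s)
  chains <- unique(s@residues$chain)
  chi <- character()
  bb <- character()
  rigid <- character()
  resolveKey <- function(tok, ln) {
    if (tok %in% keys) return(tok)
    if (grepl("^[0-9]+$", tok) && length(chains) == 1) {
      k <- .residueKey(chains[1], tok)
      if (k %in% keys) return(k)
    }
    stop("movemap line ", ln, ": residue ", tok, " not in structure")
  }
  for (ln in seq_along(lines)) {
    tok <- strsplit(lines[ln], "\\s+")[[1]]
    kind <- toupper(tok[1])
    if (kind == "RESIDUE") {
      if (length(tok) < 3) stop("malformed movemap line ", ln)
      mode <- toupper(tok[3])
      if (!mode %in% c("CHI", "BBCHI", "NO")) {
        stop("movemap line ", ln, ": unknown mode ", tok[3])
      }
      tgt <- if (tok[2] == "*") keys else resolveKey(tok[2], ln)
      if (mode %in% c("CHI", "BBCHI")) chi <- union(chi, tgt)
      if (mode == "BBCHI") bb <- union(bb, tgt)
      if (mode == "NO") {
        chi <- setdiff(chi, tgt)
        bb <- setdiff(bb, tgt)
      }
    } else if (kind == "JUMP") {
      if (length(tok) < 3) stop("malformed movemap line ", ln)
      tgt <- if (tok[2] == "*") chains else tok[2]
      if (!all(tgt %in% chains)) {
        stop("movemap line ", ln, ": chain ", tok[2], " not in structure")
      }
      if (toupper(tok[3]) == "YES") rigid <- union(rigid, tgt)
      else rigid <- setdiff(rigid, tgt)
    } else {
      stop("movemap line ", ln, ": unknown record ", tok[1])
    }
  }
  methods::new("MoveMap", chiMovable = chi, bbMovable = bb,
               rigidChains = rigid)
}

#' Emit a resfile for a set of designed positions
#'
#' Convenience writer: designed positions get `PIKAA <letters>` (or
#' `ALLAA`), the 10 Angstrom CA shell around them gets `NATAA`, and the
#' default command is `NATRO`.
#'
#' @param s a \linkS4class{ProteinStructure}.
#' @param designed character vector of designed position keys.
#' @param allowed single string of one-letter codes for `PIKAA`, or
#'   `"ALLAA"` (default) to allow all 20 types.
#' @param radius repack shell radius in Angstrom.
#' @return resfile text (single string).
#' @export
resfileForDesign <- function(s, designed, allowed = "ALLAA", radius = 10) {
  shell <- autoRepackShell(s, designed, radius)
  res <- s@residues
  lines <- c("NATRO", "start")
  for (i in seq_len(nrow(res))) {
    k <- res$key[i]
    if (k %in% designed) {
      cmd <- if (identical(allowed, "ALLAA")) "ALLAA"
             else paste("PIKAA", allowed)
      lines <- c(lines, paste(res$resno[i], res$chain[i], cmd))
    } else if (k %in% shell) {
      lines <- c(lines, paste(res$resno[i], res$chain[i], "NATAA"))
    }
  }
  paste(lines, collapse = "\n")
}
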