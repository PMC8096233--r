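#' Write a trajectory as a multi-model PDB file
#'
#' Emits standard MODEL/ENDMDL blocks with fixed-column ATOM records
#' (PDB v3.3 layout). Chain ids, residue numbers/names and atom names come
#' from the topology.
#'
#' @param traj a [TailTrajectory-class].
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeTrajectoryPdb <- function(traj, file) {
  tp <- topology(traj)
  con <- file(file, "w")
  on.exit(close(con))
  nA <- nAtoms(traj)
  serial <- seq_len(nA)
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- traj@coords[f, , , drop = TRUE]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      serial %% 100000,
      substr(sprintf(" %-3s", tp$atom), 1, 4),
      substr(tp$resname, 1, 3), tp$chain, tp$resno %% 10000,
      x[, 1], x[, 2], x[, 3], 1.00, 0.00)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL blocks via `bio3d::read.pdb` and pairs the
#' coordinates with a topology table, either supplied (from
#' [writeTopologyTsv()]) or reconstructed from the PDB fields (in which
#' case all atoms are flagged heavy unless named like hydrogens, and roles
#' are inferred: DNA chains I/J, tail residues 1-37 of protein chains,
#' core otherwise).
#'
#' @param file PDB path.
#' @param topology optional topology data.frame overriding inference.
#' @param dtPs frame spacing in ps (default 10).
#' @return A [TailTrajectory-class].
#' @export
readTrajectoryPdb <- function(file, topology = NULL, dtPs = 10) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  xyz <- pdb$xyz
  nF <- nrow(xyz)
  nA <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nF, nA, 3))
  for (f in seq_len(nF))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  if (is.null(topology)) {
    at <- pdb$atom
    isDna <- at$chain %in% c("I", "J") |
      at$resid %in% c("DA", "DT", "DG", "DC")
    role <- ifelse(isDna, "DNA",
                   ifelse(at$resno <= 37, "tail", "core"))
    topology <- data.frame(
      chain = at$chain, resno = at$resno, resname = at$resid,
      atom = trimws(at$elety),
      heavy = !grepl("^[0-9]*H", trimws(at$elety)), role = role)
  }
  new("TailTrajectory", coords = coords, topology = topology, dtPs = dtPs)
}

#' Write / read a topology table as TSV
#'
#' @param topology topology data.frame (columns `chain`, `resno`,
#'   `resname`, `atom`, `heavy`, `role`).
#' @param file path.
#' @return `writeTopologyTsv` the path invisibly; `readTopologyTsv` the
#'   data.frame.
#' @export
writeTopologyTsv <- function(topology, file) {
  write.table(topology, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTopologyTsv
#' @export
readTopologyTsv <- function(file) {
  tp <- read.delim(file, stringsAsFactors = FALSE)
  tp$heavy <- as.logical(tp$heavy)
  tp$chain <- as.character(tp$chain)
  tp
}

#' Write / read tabular results as TSV
#'
#' Plain tab-separated round trip used for gel tables, peak lists,
#' relaxation series and analysis outputs.
#'
#' @param x data.frame.
#' @param file path.
#' @return `writeTsv` the path invisibly; `readTsv` a data.frame.
#' @export
writeTsv <- function(x, file) {
  write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeTsv
#' @export
readTsv <- function(file) read.delim(file, stringsAsFactors = FALSE)

#' Read a Sparky-style amide peak list
#'
#' Expects tab- or space-separated columns: assignment string (e.g.
#' `K23N-H`), 15N shift (ppm), 1H shift (ppm), height. The residue number
#' is the integer embedded in the assignment.
#'
#' @param file path.
#' @param species species label attached to the list.
#' @return Peak-list data.frame with `species`, `residue`, `dH`, `dN`,
#'   `height`, `overlap` (TRUE for assignments marked with `*`).
#' @export
readSparkyPeaks <- function(file, species = "") {
  raw <- read.table(file, header = TRUE, stringsAsFactors = FALSE)
  stopIfNot(ncol(raw) >= 4, "expected assignment, 15N, 1H, height columns")
  assign <- as.character(raw[[1]])
  res <- as.integer(gsub("[^0-9].*$", "", gsub("^[^0-9]*", "", assign)))
  data.frame(species = species, residue = res,
             dH = as.numeric(raw[[3]]), dN = as.numeric(raw[[2]]),
             height = as.numeric(raw[[4]]),
             overlap = grepl("\\*", assign))
}

#' Read amide chemical shifts from an NMR-STAR chemical-shift loop
#'
#' Minimal reader for the `_Atom_chem_shift` loop of a BMRB NMR-STAR 3.1
#' file: extracts backbone amide H and N shifts per residue and pairs them
#' into a peak list (heights are not deposited and are set to NA).
#'
#' @param file NMR-STAR path.
#' @param species species label.
#' @return Peak-list data.frame with `species`, `residue`, `dH`, `dN`.
#' @export
readNmrStarShifts <- function(file, species = "") {
  lines <- readLines(file)
  lines <- trimws(lines)
  tagIdx <- grep("^_Atom_chem_shift\\.", lines)
  stopIfNot(length(tagIdx) > 0, "no _Atom_chem_shift loop found")
  tags <- sub("^_Atom_chem_shift\\.", "", lines[tagIdx])
  dataStart <- max(tagIdx) + 1L
  rows <- list()
  for (i in dataStart:length(lines)) {
    ln <- lines[i]
    if (ln == "" || ln == "stop_" || startsWith(ln, "#")) break
    rows[[length(rows) + 1L]] <- strsplit(ln, "[[:space:]]+")[[1]]
  }
  stopIfNot(length(rows) > 0, "empty chemical-shift loop")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- tags[seq_len(ncol(tab))]
  seqCol <- intersect(c("Seq_ID", "Comp_index_ID"), names(tab))[1]
  stopIfNot(all(c("Atom_ID", "Val") %in% names(tab)) && !is.na(seqCol),
            "chemical-shift loop lacks Seq_ID/Atom_ID/Val tags")
  tab$residue <- as.integer(tab[[seqCol]])
  tab$val <- as.numeric(tab$Val)
  h <- tab[tab$Atom_ID == "H", c("residue", "val")]
  n <- tab[tab$Atom_ID == "N", c("residue", "val")]
  common <- intersect(h$residue, n$residue)
  data.frame(species = species, residue = common,
             dH = h$val[match(common, h$residue)],
             dN = n$val[match(common, n$residue)],
             height = NA_real_, overlap = FALSE)
}
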