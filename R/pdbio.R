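## PDB-format reading (via bio3d, with the altloc occupancy rule) and a
## fixed-width writer that carries scheme numbering, insertion codes and
## provenance REMARK records.

# Read the ATOM records of a PDB file, resolving alternate locations by
# keeping the highest-occupancy conformer (first wins on ties).  Returns a
# data.frame in file order.
readPdbAtoms <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(at$o[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at[keep, , drop = FALSE]
}

# Crystal resolution from "REMARK   2 RESOLUTION." (NA when absent).
readPdbResolution <- function(path) {
  lines <- readLines(path, n = 100, warn = FALSE)
  hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(hit) == 0) return(NA_real_)
  num <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
  if (length(num) == 0) NA_real_ else as.numeric(num)
}

# Write chains to a PDB file.  `chains` is a named list (name = chain id) of
# data.frames with columns number, ins, aa, atom, x, y, z.  `remarks` lines
# are written verbatim after the header.
writePdbFile <- function(chains, path, remarks = character(0),
                         resolution = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(resolution))
    writeLines(sprintf(
      "REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", resolution), con)
  if (length(remarks)) writeLines(remarks, con)
  serial <- 0L
  for (cid in names(chains)) {
    ch <- chains[[cid]]
    for (i in seq_len(nrow(ch))) {
      serial <- serial + 1L
      name <- ch$atom[i]
      namef <- if (nchar(name) >= 4) substr(name, 1, 4)
               else sprintf(" %-3s", name)
      elem <- substr(gsub("[0-9]", "", name), 1, 1)
      writeLines(sprintf(
        "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, namef, bio3d::aa123(ch$aa[i]), cid, ch$number[i],
        ifelse(ch$ins[i] == "", " ", ch$ins[i]),
        ch$x[i], ch$y[i], ch$z[i], 1, 0, elem), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %3s %1s%4d",
                       serial, bio3d::aa123(ch$aa[nrow(ch)]), cid,
                       ch$number[nrow(ch)]), con)
  }
  writeLines("END", con)
  invisible(path)
}
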