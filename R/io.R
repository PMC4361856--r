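## Multi-model PDB and XYZ trajectory I/O.
##
## The PDB dialect is deliberately minimal: MODEL/ENDMDL delimited frames,
## chain A for the peptide (glycan atoms as a HETATM group on the
## glycosylated residue), chains U/L for upper/lower-leaflet lipids. Lipid
## atom names encode roles: "P" phosphate, "N" choline nitrogen,
## "C<k>A"/"C<k>B" acyl carbons of chains c1/c2, "F<k>X"/"G<k>X" the two
## hydrogens attached to carbon k. No CONECT perception, no altlocs.

.format_pdb_name <- function(name) {
  ifelse(nchar(name) <= 3L, sprintf(" %-3s", name), sprintf("%-4s", name))
}

#' Write a trajectory to disk
#'
#' Emits either a multi-model PDB (one MODEL/ENDMDL block per frame, CRYST1
#' when a box is present) or plain per-frame XYZ blocks. Output is
#' re-readable by [read_structure()] with coordinates equal at format
#' precision (1e-3 Angstrom for PDB, 1e-6 for XYZ), and rewriting a re-read
#' file reproduces it byte for byte.
#'
#' @param traj an `mg_trajectory`.
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  at <- traj$topology$atoms
  nf <- n_frames(traj)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  lines <- character(0L)
  if (format == "pdb") {
    if (!is.null(traj$box)) {
      b <- traj$box[1L, ]
      lines <- c(lines, sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        b[1L], b[2L], b[3L], 90, 90, 90))
    }
    record <- ifelse(at$role == "glycan", "HETATM", "ATOM")
    name4 <- .format_pdb_name(at$name)
    for (i in seq_len(nf)) {
      xyz <- traj$coords[, , i, drop = TRUE]
      lines <- c(lines, sprintf("MODEL     %4d", i), sprintf(
        "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        record, seq_len(nrow(at)), name4, "", at$res_name, at$chain,
        at$res_id, "", xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, at$element),
        "ENDMDL")
    }
    lines <- c(lines, "END")
  } else {
    for (i in seq_len(nf)) {
      xyz <- traj$coords[, , i, drop = TRUE]
      lines <- c(lines, sprintf("%d", nrow(at)), sprintf("frame %d", i),
                 sprintf("%-2s %13.6f %13.6f %13.6f",
                         at$element, xyz[, 1L], xyz[, 2L], xyz[, 3L]))
    }
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a structure/trajectory file
#'
#' Parses a multi-model PDB (this package's dialect, see
#' [write_trajectory()]) or an XYZ file with frame blocks. Atom roles are
#' recovered from chain IDs and atom names for PDB; XYZ carries no role
#' information, so its topology holds only element names.
#'
#' @param path file to read.
#' @param format `"pdb"` or `"xyz"`.
#' @return list with elements `topology` (`mg_topology`) and `trajectory`
#'   (`mg_trajectory`, one frame per model/frame block).
#' @export
read_structure <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") .read_pdb(lines, path) else .read_xyz(lines, path)
}

.num_field <- function(line, from, to, lineno, what) {
  v <- suppressWarnings(as.numeric(substr(line, from, to)))
  if (is.na(v))
    stop("malformed ", what, " at line ", lineno, ": '", line, "'")
  v
}

.read_pdb <- function(lines, path) {
  box <- NULL
  models <- list()
  meta <- NULL
  cur <- NULL       # list of per-atom rows for current model
  in_model <- FALSE
  seen_model_kw <- any(startsWith(lines, "MODEL"))
  flush_model <- function() {
    if (is.null(cur) || length(cur$x) == 0L) return()
    m <- cbind(cur$x, cur$y, cur$z)
    if (length(models) > 0L && nrow(m) != nrow(models[[1L]]))
      stop("structural error: model ", length(models) + 1L, " has ",
           nrow(m), " atoms, expected ", nrow(models[[1L]]))
    models[[length(models) + 1L]] <<- m
    if (is.null(meta)) meta <<- cur$meta
    cur <<- NULL
  }
  new_model <- function() cur <<- list(x = numeric(), y = numeric(),
                                       z = numeric(), meta = NULL)
  new_model()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- substr(line, 1L, 6L)
    if (startsWith(rec, "CRYST1")) {
      box <- c(.num_field(line, 7, 15, ln, "CRYST1 record"),
               .num_field(line, 16, 24, ln, "CRYST1 record"),
               .num_field(line, 25, 33, ln, "CRYST1 record"))
    } else if (startsWith(rec, "MODEL")) {
      flush_model(); new_model()
    } else if (startsWith(rec, "ENDMDL")) {
      flush_model(); new_model()
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (nchar(line) < 54L)
        stop("malformed ATOM record at line ", ln, ": '", line, "'")
      cur$x <- c(cur$x, .num_field(line, 31, 38, ln, "ATOM record"))
      cur$y <- c(cur$y, .num_field(line, 39, 46, ln, "ATOM record"))
      cur$z <- c(cur$z, .num_field(line, 47, 54, ln, "ATOM record"))
      if (is.null(meta)) {
        row <- data.frame(
          name = trimws(substr(line, 13, 16)),
          res_name = trimws(substr(line, 18, 20)),
          res_id = as.integer(.num_field(line, 23, 26, ln, "residue number")),
          chain = substr(line, 22, 22),
          element = trimws(substr(line, 77, 78)),
          stringsAsFactors = FALSE)
        cur$meta <- rbind(cur$meta, row)
      }
    }
  }
  flush_model()
  if (length(models) == 0L) stop("no atoms found in ", path)
  if (!seen_model_kw && length(models) > 1L)
    stop("structural error: multiple frames without MODEL records")
  top <- .classify_pdb_atoms(meta)
  traj <- mg_trajectory(top, models, box = box)
  list(topology = top, trajectory = traj)
}

.classify_pdb_atoms <- function(meta) {
  n <- nrow(meta)
  segment <- ifelse(meta$chain %in% c("U", "L"), "lipid", "peptide")
  segment[meta$res_name == "GLC"] <- "peptide"
  role <- rep("other", n)
  acyl <- rep(NA_character_, n)
  carbon <- rep(NA_integer_, n)
  lipid_id <- rep(NA_integer_, n)
  leaflet <- rep(NA_character_, n)
  is_lip <- segment == "lipid"
  lipid_id[is_lip] <- meta$res_id[is_lip]
  leaflet[is_lip] <- ifelse(meta$chain[is_lip] == "U", "upper", "lower")
  nm <- meta$name
  role[is_lip & nm == "P"] <- "phosphate"
  role[is_lip & nm == "N"] <- "choline"
  ch_c <- is_lip & grepl("^C[0-9]+[AB]$", nm)
  ch_h <- is_lip & grepl("^[FG][0-9]+[AB]$", nm)
  role[ch_c] <- "carbon"
  role[ch_h] <- "hydrogen"
  idx <- ch_c | ch_h
  carbon[idx] <- as.integer(gsub("^[CFG]([0-9]+)[AB]$", "\\1", nm[idx]))
  acyl[idx] <- ifelse(grepl("A$", nm[idx]), "c1", "c2")
  is_pep <- segment == "peptide"
  role[is_pep & meta$res_name == "GLC"] <- "glycan"
  role[is_pep & nm == "CA"] <- "ca"
  role[is_pep & nm %in% c("N", "C", "O")] <- "backbone"
  role[is_pep & role == "other"] <- "sidechain"
  element <- meta$element
  fallback <- element == "" | is.na(element)
  guess <- substr(gsub("[^A-Za-z].*$", "", nm), 1L, 1L)
  guess[role == "hydrogen"] <- "H"
  guess[role == "glycan"] <- "C"
  element[fallback] <- guess[fallback]
  pep_res <- meta$res_id[is_pep]
  glyc <- unique(meta$res_id[role == "glycan"])
  hc <- if (length(pep_res) > 0L && max(pep_res) >= 12L) c(5L, 12L)
        else if (length(pep_res) > 0L) c(1L, max(pep_res)) else c(5L, 12L)
  mg_topology(
    data.frame(name = nm, res_name = meta$res_name, res_id = meta$res_id,
               chain = meta$chain, segment = segment, role = role,
               element = element, lipid_id = lipid_id, leaflet = leaflet,
               acyl = acyl, carbon = carbon, stringsAsFactors = FALSE),
    helix_core = hc,
    glycan_residue = if (length(glyc) > 0L) glyc[1L] else NA_integer_)
}

.read_xyz <- function(lines, path) {
  models <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[[i]]) == "") { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(na) || na < 1L)
      stop("malformed XYZ atom count at line ", i, ": '", lines[[i]], "'")
    if (i + 1L + na > length(lines))
      stop("structural error: truncated XYZ frame starting at line ", i)
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad) > 0L)
      stop("malformed XYZ record at line ", i + 1L + bad[1L], ": '",
           block[bad[1L]], "'")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      v
    }, numeric(3L)))
    if (anyNA(xyz))
      stop("malformed XYZ coordinates in frame starting at line ", i)
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("structural error: XYZ frame at line ", i,
           " has ", na, " atoms, expected ", length(elements))
    models[[length(models) + 1L]] <- xyz
    i <- i + 2L + na
  }
  if (length(models) == 0L) stop("no atoms found in ", path)
  n <- length(elements)
  top <- mg_topology(data.frame(
    name = elements, res_name = "UNK", res_id = 1L, chain = "X",
    segment = "other", role = "unknown", element = elements,
    lipid_id = NA_integer_, leaflet = NA_character_,
    acyl = NA_character_, carbon = NA_integer_, stringsAsFactors = FALSE),
    helix_core = c(1L, 1L))
  list(topology = top, trajectory = mg_trajectory(top, models))
}
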