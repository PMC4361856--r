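#' Build an atom selection
#'
#' Resolves a named selection rule (or an explicit index list) against a
#' topology. Rules are strings of the form `"<role>[:<residues>]"`:
#'
#' * `"peptide_ca"` — all peptide Calpha atoms; an optional residue list
#'   restricts it, e.g. `"peptide_ca:5-12"` or `"peptide_ca:3,6,7,18"`.
#' * `"peptide_core_ca"` — Calpha atoms of the topology's helix core.
#' * `"glycan"` — glycan atoms.
#' * `"membrane_p"` — lipid phosphate atoms (the PO4 marker atom per lipid).
#' * `"choline_n"` — choline nitrogens.
#' * `"lipid_carbons:c1"` / `"lipid_carbons:c2"` — acyl-chain carbons.
#'
#' Explicit numeric input is taken as 1-based atom indices and must be
#' duplicate-free and in range. Selections are returned sorted, so the same
#' `(topology, spec)` pair always yields an identical object.
#'
#' @param topology an `mg_topology`.
#' @param spec rule string or numeric index vector.
#' @param name optional label; defaults to the rule text.
#' @param allow_empty return an empty selection instead of erroring.
#' @return object of class `mg_selection` with fields `name` and `indices`.
#' @export
build_selection <- function(topology, spec, name = NULL, allow_empty = FALSE) {
  at <- topology$atoms
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
    if (anyDuplicated(idx) > 0L)
      stop("explicit selection contains duplicate indices")
    if (any(idx < 1L | idx > nrow(at)))
      stop("explicit selection index out of range for this topology")
    label <- name %||% "explicit"
  } else if (is.character(spec) && length(spec) == 1L) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    rule <- parts[1L]
    arg <- if (length(parts) > 1L) parts[2L] else NULL
    idx <- switch(rule,
      peptide_ca = {
        sel <- at$segment == "peptide" & at$role == "ca"
        if (!is.null(arg)) sel <- sel & at$res_id %in% .parse_residues(arg)
        which(sel)
      },
      peptide_core_ca = {
        hc <- topology$helix_core
        which(at$segment == "peptide" & at$role == "ca" &
              at$res_id >= hc[1L] & at$res_id <= hc[2L])
      },
      glycan = which(at$role == "glycan"),
      membrane_p = which(at$role == "phosphate"),
      choline_n = which(at$role == "choline"),
      lipid_carbons = {
        if (is.null(arg) || !arg %in% c("c1", "c2"))
          stop("lipid_carbons needs an acyl chain argument, c1 or c2")
        which(at$role == "carbon" & at$acyl == arg)
      },
      stop("unknown selection rule: '", rule, "'"))
    label <- name %||% spec
  } else {
    stop("selection spec must be a rule string or a numeric index vector")
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0L && !allow_empty)
    stop("selection '", name %||% "(explicit)",
         "' resolved to zero atoms")
  structure(list(name = label, indices = as.integer(idx)),
            class = "mg_selection")
}

.parse_residues <- function(arg) {
  out <- integer(0L)
  for (piece in strsplit(arg, ",", fixed = TRUE)[[1L]]) {
    piece <- trimws(piece)
    if (grepl("^[0-9]+-[0-9]+$", piece)) {
      ab <- as.integer(strsplit(piece, "-", fixed = TRUE)[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else if (grepl("^[0-9]+$", piece)) {
      out <- c(out, as.integer(piece))
    } else {
      stop("cannot parse residue list piece: '", piece, "'")
    }
  }
  out
}

#' @export
print.mg_selection <- function(x, ...) {
  cat("mg_selection '", x$name, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}
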