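## System topology: one flat atom table plus peptide annotations.
## Atom roles: ca, backbone, sidechain, glycan (peptide);
##             phosphate, choline, carbon, hydrogen (lipid).

.topology_cols <- c("name", "res_name", "res_id", "chain", "segment", "role",
                    "element", "lipid_id", "leaflet", "acyl", "carbon")

#' Assemble a system topology
#'
#' A topology binds every atom of the system to its chemical role so that
#' selections ("peptide Calpha", "membrane phosphate atoms", "c1 chain
#' carbons") resolve deterministically. Peptide and lipid atoms live in one
#' flat table; peptide-level annotations (helix core range, glycosylated
#' residue) are carried alongside.
#'
#' @param atoms data.frame with columns `name`, `res_name`, `res_id`,
#'   `chain`, `segment` (`"peptide"` or `"lipid"`), `role`, `element`,
#'   `lipid_id`, `leaflet` (`"upper"`/`"lower"`/`NA`), `acyl`
#'   (`"c1"`/`"c2"`/`NA`) and `carbon` (acyl carbon index or `NA`).
#' @param helix_core inclusive residue index range of the structured helix
#'   core used for RMSD work; default residues 5 to 12.
#' @param glycan_residue residue index carrying the glycan, or `NA`.
#' @return an object of class `mg_topology`.
#' @export
mg_topology <- function(atoms, helix_core = c(5L, 12L),
                        glycan_residue = NA_integer_) {
  missing <- setdiff(.topology_cols, names(atoms))
  if (length(missing) > 0L)
    stop("topology atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  top <- structure(
    list(atoms = atoms,
         helix_core = as.integer(helix_core),
         glycan_residue = as.integer(glycan_residue)[1L]),
    class = "mg_topology")
  validate_topology(top)
  top
}

#' Validate topology invariants
#'
#' Checks residue contiguity, the one-Calpha-per-residue rule, the helix-core
#' range, uniqueness of acyl carbon indices per chain per lipid, and that
#' leaflet labels partition the lipids. Called by [mg_topology()]; exported
#' so readers can re-validate after manual edits.
#'
#' @param top an `mg_topology`.
#' @return `top`, invisibly; errors on violation.
#' @export
validate_topology <- function(top) {
  at <- top$atoms
  pep <- at[at$segment == "peptide", , drop = FALSE]
  if (nrow(pep) > 0L) {
    res <- sort(unique(pep$res_id))
    if (!identical(res, seq_len(length(res))))
      stop("peptide residue indices must be contiguous starting at 1")
    ca_per_res <- table(factor(pep$res_id[pep$role == "ca"], levels = res))
    if (any(ca_per_res != 1L))
      stop("each peptide residue must have exactly one Calpha atom")
    hc <- top$helix_core
    if (length(hc) != 2L || hc[1L] > hc[2L] ||
        hc[1L] < min(res) || hc[2L] > max(res))
      stop("helix_core range must lie within the peptide residue range")
    if (!is.na(top$glycan_residue) &&
        !(top$glycan_residue %in% res))
      stop("glycan_residue outside peptide residue range")
  }
  lip <- at[at$segment == "lipid", , drop = FALSE]
  if (nrow(lip) > 0L) {
    if (anyNA(lip$lipid_id)) stop("lipid atoms must carry a lipid_id")
    leaf <- unique(lip[, c("lipid_id", "leaflet")])
    if (anyNA(leaf$leaflet) || anyDuplicated(leaf$lipid_id) > 0L)
      stop("leaflet labels must partition the lipids")
    carbons <- lip[lip$role == "carbon", , drop = FALSE]
    if (nrow(carbons) > 0L) {
      key <- paste(carbons$lipid_id, carbons$acyl, carbons$carbon)
      if (anyDuplicated(key) > 0L)
        stop("acyl carbon index repeated within a chain of one lipid")
    }
  }
  invisible(top)
}

#' @export
print.mg_topology <- function(x, ...) {
  at <- x$atoms
  pep <- at[at$segment == "peptide", , drop = FALSE]
  lip <- at[at$segment == "lipid", , drop = FALSE]
  cat("mg_topology:", nrow(at), "atoms\n")
  if (nrow(pep) > 0L)
    cat("  peptide:", length(unique(pep$res_id)), "residues; helix core ",
        x$helix_core[1L], "-", x$helix_core[2L],
        if (!is.na(x$glycan_residue))
          paste0("; glycan at residue ", x$glycan_residue) else "", "\n",
        sep = "")
  if (nrow(lip) > 0L)
    cat("  lipids:", length(unique(lip$lipid_id)), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top an `mg_topology`.
#' @return integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Peptide residue table
#' @param top an `mg_topology`.
#' @return data.frame with columns `res_id`, `res_name` (one row per residue).
#' @export
peptide_residues <- function(top) {
  pep <- top$atoms[top$atoms$segment == "peptide" & top$atoms$role == "ca",
                   c("res_id", "res_name")]
  pep[order(pep$res_id), , drop = FALSE]
}

#' CSF114-style fixture sequence
#'
#' 21-residue sequence of the glycopeptide fixture. Only the residue
#' identities that are unambiguous for this peptide are encoded; the
#' remaining positions (2, 10, 11, 17, 19, 20) are alanine placeholders,
#' flagged via the `placeholder` attribute. The asparagine at position 7
#' carries the N-linked glucose.
#'
#' @return character vector of 21 three-letter residue codes with attributes
#'   `placeholder` (logical vector) and `glycan_residue` (7).
#' @export
csf114_sequence <- function() {
  seq <- c("THR", "ALA", "ARG", "VAL", "GLU", "ARG", "ASN", "GLY", "HIS",
           "ALA", "ALA", "PHE", "TYR", "ALA", "PRO", "TYR", "ALA", "TRP",
           "ALA", "ALA", "LYS")
  placeholder <- seq_along(seq) %in% c(2L, 10L, 11L, 17L, 19L, 20L)
  structure(seq, placeholder = placeholder, glycan_residue = 7L)
}

## Residue interaction class used by the coarse simulator:
## glycan beads bind strongest, then basic, then aromatic side chains.
residue_class <- function(res_name) {
  ifelse(res_name == "GLC", "glycan",
  ifelse(res_name %in% c("ARG", "LYS", "HIS"), "basic",
  ifelse(res_name %in% c("TRP", "TYR", "PHE"), "aromatic", "other")))
}

## Minimal Calpha-only peptide topology (used by cluster fixtures).
make_ca_topology <- function(n_res, helix_core = NULL,
                             res_names = rep("ALA", n_res)) {
  if (is.null(helix_core)) helix_core <- c(1L, n_res)
  atoms <- data.frame(
    name = "CA", res_name = res_names, res_id = seq_len(n_res),
    chain = "A", segment = "peptide", role = "ca", element = "C",
    lipid_id = NA_integer_, leaflet = NA_character_,
    acyl = NA_character_, carbon = NA_integer_,
    stringsAsFactors = FALSE)
  mg_topology(atoms, helix_core = helix_core)
}
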