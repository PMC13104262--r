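CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Lipinski-style ligand filter
#'
#' A ligand descriptor record passes iff molecular weight <= 500 Da,
#' logP <= 5, hydrogen-bond donors <= 5 and hydrogen-bond acceptors <= 10
#' (all thresholds inclusive). Descriptor computation from structures is an
#' adapter's job (e.g. RDKit/ChemmineR with its documented logP dialect);
#' this filter consumes numeric records so it is testable without a
#' chemistry toolkit.
#'
#' @param molWeight Da; positive.
#' @param logp unitless.
#' @param hbd,hba non-negative integer counts.
#' @return logical vector.
#' @export
ligandPasses <- function(molWeight, logp, hbd, hba) {
  if (anyNA(c(molWeight, logp, hbd, hba)))
    stop("missing ligand descriptor; a ligand never passes by default")
  if (any(molWeight <= 0)) stop("molWeight must be positive")
  if (any(hbd < 0) || any(hba < 0)) stop("hbd/hba must be non-negative")
  molWeight <= 500 & logp <= 5 & hbd <= 5 & hba <= 10
}

#' Canonical-residue protein filter
#'
#' A protein passes iff every residue code is one of the 20 canonical
#' one-letter amino-acid codes. Ambiguity codes (B, Z, X) and noncanonical
#' residues (U selenocysteine, O pyrrolysine) all fail.
#'
#' @param sequences character vector of residue-code strings (or an
#'   \code{AAStringSet}).
#' @return logical vector.
#' @export
proteinPasses <- function(sequences) {
  sequences <- as.character(sequences)
  if (any(!nzchar(sequences))) stop("empty residue record")
  vapply(strsplit(toupper(sequences), ""),
         function(s) all(s %in% CANONICAL_AA), TRUE)
}

#' Two-stage complex curation
#'
#' Applies the canonical-residue protein check and the Lipinski-style
#' ligand thresholds to matched records; complexes failing any criterion
#' are removed. The rejection report lists each removed id with the first
#' failed criterion (protein first, then mol_weight, logp, hbd, hba).
#'
#' @param proteins data.frame with columns \code{instance_id},
#'   \code{sequence}.
#' @param ligands data.frame with columns \code{instance_id},
#'   \code{mol_weight}, \code{logp}, \code{hbd}, \code{hba}.
#' @return list with \code{retained} (character ids, input order) and
#'   \code{report} (data.frame \code{instance_id}, \code{reason}).
#' @export
curateComplexes <- function(proteins, ligands) {
  if (!setequal(proteins$instance_id, ligands$instance_id))
    stop("protein and ligand records must cover the same instance ids; ",
         "mismatched: ",
         paste(head(c(setdiff(proteins$instance_id, ligands$instance_id),
                      setdiff(ligands$instance_id, proteins$instance_id)), 5),
               collapse = ", "))
  lig <- ligands[match(proteins$instance_id, ligands$instance_id), ]
  okP <- proteinPasses(proteins$sequence)
  crit <- list(mol_weight = lig$mol_weight > 500, logp = lig$logp > 5,
               hbd = lig$hbd > 5, hba = lig$hba > 10)
  ## first failed criterion in fixed order; one entry per rejected complex
  reasons <- rep(NA_character_, nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    if (!okP[i]) { reasons[i] <- "protein_noncanonical"; next }
    for (nm in names(crit)) if (crit[[nm]][i]) { reasons[i] <- nm; break }
  }
  rejected <- !is.na(reasons)
  list(retained = proteins$instance_id[!rejected],
       report = data.frame(instance_id = proteins$instance_id[rejected],
                           reason = reasons[rejected]))
}

#' Read residue records from FASTA
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet} returning the
#' data.frame shape \code{curateComplexes} consumes.
#'
#' @param fastaPath path to an uncompressed FASTA file.
#' @return data.frame with \code{instance_id}, \code{sequence}.
#' @export
readResidueRecords <- function(fastaPath) {
  aa <- Biostrings::readAAStringSet(fastaPath)
  data.frame(instance_id = names(aa), sequence = as.character(aa),
             row.names = NULL)
}

#' Read ligand descriptor CSV
#'
#' Schema: \code{instance_id,mol_weight,logp,hbd,hba}.
#'
#' @param csvPath path.
#' @return data.frame.
#' @export
readLigandDescriptors <- function(csvPath) {
  df <- read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("instance_id", "mol_weight", "logp", "hbd", "hba")
  if (!all(need %in% names(df)))
    stop("descriptor CSV must have columns ", paste(need, collapse = ", "))
  df
}
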