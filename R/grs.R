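#' Read an external variant weight table
#'
#' Reads a tab-separated weight table with header columns `rsid`,
#' `effect_allele`, `other_allele`, `weight` (per-allele effect on the
#' exposure, ng/mL) and `eaf` (effect-allele frequency). External weights —
#' estimated in an independent sample — avoid the bias that arises from
#' weighting an allele score with internally estimated effects.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `variant_weights`, in file order.
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("rsid", "effect_allele", "other_allele", "weight", "eaf")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    vd_stop(
      sprintf("weight table is missing column(s): %s", paste(missing, collapse = ", ")),
      "vitdmr_parse_error"
    )
  }
  if (!is.numeric(tab$weight) || any(!is.finite(tab$weight))) {
    vd_stop("weight column must be numeric and finite", "vitdmr_parse_error")
  }
  if (!is.numeric(tab$eaf) || any(!is.finite(tab$eaf)) || any(tab$eaf <= 0 | tab$eaf >= 1)) {
    vd_stop("eaf column must be numeric in (0, 1)", "vitdmr_parse_error")
  }
  dup <- unique(tab$rsid[duplicated(tab$rsid)])
  if (length(dup)) {
    vd_stop(
      sprintf("duplicated rsid(s) in weight table: %s", paste(dup, collapse = ", ")),
      "vitdmr_parse_error"
    )
  }
  if (any(tab$effect_allele == tab$other_allele)) {
    vd_stop("effect_allele must differ from other_allele", "vitdmr_parse_error")
  }
  tab <- tab[required]
  class(tab) <- c("variant_weights", "data.frame")
  tab
}

#' @rdname read_weights
#' @param weights A `variant_weights` table to write.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(as.data.frame(weights), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

ambiguous_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize external weights to the cohort's allele coding
#'
#' Aligns a weight table to the effect/other allele coding used by the cohort
#' genotypes. Where the cohort coding is flipped relative to the weight table
#' (effect and other alleles swapped), the dosage `g` must be interpreted as
#' `2 - g`; this is recorded by negating the weight, adding a per-variant
#' constant offset of `2 * weight` (so scores equal the hand-computed `2 - g`
#' substitution exactly), swapping the allele columns, and setting
#' `flipped = TRUE`. Strand-ambiguous palindromic variants (A/T, C/G) cannot
#' be aligned reliably and are excluded with a warning by default.
#'
#' @param weights A `variant_weights` table (see [read_weights()]).
#' @param cohort_alleles `data.frame` with columns `rsid`, `effect_allele`,
#'   `other_allele` describing the cohort's dosage coding.
#' @param ambiguous `"exclude"` (default) drops strand-ambiguous variants with
#'   a warning; `"keep"` retains them flagged `ambiguous = TRUE`.
#' @return A `variant_weights` table aligned to the cohort coding, with extra
#'   columns `flipped`, `offset`, `ambiguous`, ordered as in `weights`.
#' @export
harmonize <- function(weights, cohort_alleles, ambiguous = c("exclude", "keep")) {
  ambiguous <- match.arg(ambiguous)
  idx <- match(weights$rsid, cohort_alleles$rsid)
  if (anyNA(idx)) {
    vd_stop(
      sprintf(
        "variant(s) absent from cohort allele map: %s",
        paste(weights$rsid[is.na(idx)], collapse = ", ")
      ),
      "vitdmr_harmonize_error"
    )
  }
  ca <- cohort_alleles[idx, ]
  out <- as.data.frame(weights)
  out$flipped <- FALSE
  out$offset <- 0
  out$ambiguous <- ambiguous_pair(out$effect_allele, out$other_allele)

  same <- out$effect_allele == ca$effect_allele & out$other_allele == ca$other_allele
  swap <- out$effect_allele == ca$other_allele & out$other_allele == ca$effect_allele
  bad <- !same & !swap
  if (any(bad)) {
    vd_stop(
      sprintf(
        "allele codes do not match in either orientation for: %s",
        paste(out$rsid[bad], collapse = ", ")
      ),
      "vitdmr_harmonize_error"
    )
  }
  if (any(swap)) {
    out$offset[swap] <- 2 * out$weight[swap]
    out$weight[swap] <- -out$weight[swap]
    ea <- out$effect_allele[swap]
    out$effect_allele[swap] <- out$other_allele[swap]
    out$other_allele[swap] <- ea
    out$eaf[swap] <- 1 - out$eaf[swap]
    out$flipped[swap] <- TRUE
  }
  if (any(out$ambiguous)) {
    if (ambiguous == "exclude") {
      warning(
        sprintf(
          "excluding %d strand-ambiguous variant(s): %s",
          sum(out$ambiguous), paste(out$rsid[out$ambiguous], collapse = ", ")
        ),
        call. = FALSE
      )
      out <- out[!out$ambiguous, , drop = FALSE]
    } else {
      warning(
        sprintf("%d strand-ambiguous variant(s) retained and flagged", sum(out$ambiguous)),
        call. = FALSE
      )
    }
  }
  rownames(out) <- NULL
  class(out) <- c("variant_weights", "data.frame")
  out
}

#' Compute the weighted genetic risk score
#'
#' Per-individual score `sum_j dosage_ij * weight_j` (plus any harmonization
#' offsets), in ng/mL-scale units. The dosage matrix must already be aligned
#' with the weight table (same variants, same order, same allele coding — see
#' [harmonize()]).
#'
#' @param dosages Numeric matrix, individuals x variants, values in `[0, 2]`.
#' @param weights A `variant_weights` table with one row per dosage column.
#' @return Numeric vector of scores, one per individual.
#' @export
compute_grs <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(weights)) {
    vd_stop(
      sprintf(
        "dosage matrix has %d columns but weight table has %d rows",
        ncol(dosages), nrow(weights)
      ),
      "vitdmr_dimension_error"
    )
  }
  offset <- if ("offset" %in% names(weights)) sum(weights$offset) else 0
  drop(dosages %*% weights$weight) + offset
}
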