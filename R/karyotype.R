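# Chromosome units, rearrangement polarization, and eligibility filters.
#
# A "chromosome unit" is a homology unit linking one chromosome of the fused
# (Swedish, SWE) karyotype to one or two chromosomes of the unfused (Catalan,
# CAT) karyotype of Leptidea sinapis. Rearrangements are polarized by
# parsimony against the outgroup states of L. reali and L. juvernica.

#' Fusion states and rearrangement classes
#'
#' `fusion_states()` and `rearrangement_classes()` return the valid level
#' sets used throughout the package. A unit's fusion state per taxon is one
#' of `FUSED`, `UNFUSED` or `POLYMORPHIC` (both states segregating within
#' the taxon). Rearrangement classes are: `FISSION_CAT` (derived fission in
#' the Catalan lineage), `FUSION_SWE` (derived fusion in the Swedish
#' lineage), `UNKNOWN_POLARIZATION` (fused/unfused polymorphism segregating
#' in all three species, or outgroup disagreement), `HOMOLOGOUS` (no
#' rearrangement between the populations), `SEX_Z` (Z chromosome unit) and
#' `EXCLUDED_COMPLEX` (configurations outside the single-event 1:2 model).
#'
#' @return Character vector of valid values.
#' @export
fusion_states <- function() c("FUSED", "UNFUSED", "POLYMORPHIC")

#' @rdname fusion_states
#' @export
rearrangement_classes <- function() {
  c("FISSION_CAT", "FUSION_SWE", "UNKNOWN_POLARIZATION", "HOMOLOGOUS",
    "SEX_Z", "EXCLUDED_COMPLEX")
}

# classes entering the distortion scan
autosomal_classes <- function() {
  c("FISSION_CAT", "FUSION_SWE", "UNKNOWN_POLARIZATION", "HOMOLOGOUS")
}

#' Polarize a rearrangement by parsimony
#'
#' Classifies a chromosome unit from its fusion states in the two focal
#' populations (SWE, CAT) and the two outgroup species (*L. reali*,
#' *L. juvernica*). The focal populations must be scored `FUSED` or
#' `UNFUSED`; outgroups may additionally be `POLYMORPHIC`.
#'
#' Rules: identical focal states give `HOMOLOGOUS`. For the common
#' SWE-fused / CAT-unfused configuration, two unfused outgroups imply a
#' derived fusion in SWE (`FUSION_SWE`), two fused outgroups a derived
#' fission in CAT (`FISSION_CAT`); a polymorphic outgroup or outgroup
#' disagreement cannot be polarized by parsimony (`UNKNOWN_POLARIZATION`).
#' The reverse configuration (SWE unfused, CAT fused) falls outside the
#' study's single-event model and is marked `EXCLUDED_COMPLEX`.
#'
#' @param state_swe,state_cat Fusion state of the Swedish / Catalan
#'   population (`FUSED` or `UNFUSED`).
#' @param state_reali,state_juvernica Outgroup fusion states (`FUSED`,
#'   `UNFUSED` or `POLYMORPHIC`).
#' @return Character vector of rearrangement classes (vectorized over
#'   inputs).
#' @examples
#' classify_unit("FUSED", "UNFUSED", "UNFUSED", "UNFUSED") # FUSION_SWE
#' classify_unit("FUSED", "UNFUSED", "FUSED", "FUSED")     # FISSION_CAT
#' @export
classify_unit <- function(state_swe, state_cat, state_reali,
                          state_juvernica) {
  args <- list(state_swe = state_swe, state_cat = state_cat,
               state_reali = state_reali, state_juvernica = state_juvernica)
  n <- max(lengths(args))
  args <- lapply(args, rep_len, n)
  for (taxon in names(args)) {
    v <- args[[taxon]]
    if (anyNA(v)) {
      stop(sprintf("missing fusion state for taxon '%s'",
                   sub("state_", "", taxon)), call. = FALSE)
    }
    ok <- if (taxon %in% c("state_swe", "state_cat")) {
      c("FUSED", "UNFUSED")
    } else {
      fusion_states()
    }
    if (!all(v %in% ok)) {
      stop(sprintf("invalid fusion state for taxon '%s': %s",
                   sub("state_", "", taxon),
                   paste(setdiff(unique(v), ok), collapse = ", ")),
           call. = FALSE)
    }
  }
  swe <- args$state_swe; cat_ <- args$state_cat
  out1 <- args$state_reali; out2 <- args$state_juvernica

  klass <- character(n)
  same <- swe == cat_
  klass[same] <- "HOMOLOGOUS"
  rev <- swe == "UNFUSED" & cat_ == "FUSED"
  klass[rev] <- "EXCLUDED_COMPLEX"
  het <- swe == "FUSED" & cat_ == "UNFUSED"
  both_unfused <- het & out1 == "UNFUSED" & out2 == "UNFUSED"
  both_fused <- het & out1 == "FUSED" & out2 == "FUSED"
  klass[both_unfused] <- "FUSION_SWE"
  klass[both_fused] <- "FISSION_CAT"
  klass[het & !both_unfused & !both_fused] <- "UNKNOWN_POLARIZATION"
  klass
}

#' Construct a karyotype of chromosome units
#'
#' Builds and validates the unit table used by the simulator and the
#' distortion scan. Each row links one SWE chromosome to the CAT
#' chromosome(s) it is homologous to.
#'
#' @param units A data.frame with columns `unit_id`, `swe_chrom`,
#'   `cat_chroms` (one id, or several joined by `";"`), the four fusion
#'   state columns `state_swe`, `state_cat`, `state_reali`,
#'   `state_juvernica`, and logical `is_sex`. A `class` column is
#'   recomputed from the states unless `is_sex` is set (sex units are
#'   always `SEX_Z`) or the class is `EXCLUDED_COMPLEX` with more than two
#'   CAT chromosomes.
#' @return The validated data.frame with classes `karyotype` and
#'   `data.frame`, with columns `class` and `n_cat` filled in.
#' @export
karyotype <- function(units) {
  stopifnot(is.data.frame(units))
  required <- c("unit_id", "swe_chrom", "cat_chroms", "state_swe",
                "state_cat", "state_reali", "state_juvernica", "is_sex")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols)) {
    stop("unit table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  if (anyDuplicated(units$unit_id)) {
    stop("duplicated unit_id in karyotype", call. = FALSE)
  }
  units$n_cat <- lengths(strsplit(units$cat_chroms, ";", fixed = TRUE))
  if (any(units$n_cat < 1L)) {
    stop("every unit needs at least one CAT chromosome", call. = FALSE)
  }
  units$class <- ifelse(
    units$is_sex, "SEX_Z",
    classify_unit(units$state_swe, units$state_cat, units$state_reali,
                  units$state_juvernica))
  # more than one event stacked on a unit cannot be ordered -> complex
  units$class[!units$is_sex & units$n_cat > 2L] <- "EXCLUDED_COMPLEX"
  bad <- units$class %in% c("FISSION_CAT", "FUSION_SWE",
                            "UNKNOWN_POLARIZATION") & units$n_cat == 1L
  if (any(bad)) {
    stop("rearranged unit with a single CAT chromosome: ",
         paste(units$unit_id[bad], collapse = ", "), call. = FALSE)
  }
  class(units) <- c("karyotype", "data.frame")
  units
}

#' Number of Z chromosome units in a karyotype
#' @param kar A `karyotype`.
#' @return Integer count of sex units.
#' @export
n_z_units <- function(kar) sum(kar$is_sex)

#' Units eligible for the transmission distortion scan
#'
#' Applies the study's eligibility filters: Z chromosome units are removed
#' (they are monomorphic for the SWE state in the backcross, and excluded
#' in both cross designs here), complex rearrangements are removed, and
#' units must have the simple 1:2 (rearranged) or 1:1 (homologous)
#' SWE:CAT chromosome ratio so that the two populations differ by at most
#' a single fission/fusion event.
#'
#' @param kar A `karyotype`.
#' @param cross `"backcross"` or `"intercross"`. The filter is identical
#'   for both designs; the argument documents intent and future-proofs
#'   design-specific filters.
#' @return The eligible subset of the unit table (possibly zero rows).
#' @export
eligible_units <- function(kar, cross = c("backcross", "intercross")) {
  cross <- match.arg(cross)
  keep <- !kar$is_sex &
    kar$class %in% autosomal_classes() &
    ((kar$class == "HOMOLOGOUS" & kar$n_cat == 1L) |
     (kar$class != "HOMOLOGOUS" & kar$n_cat == 2L))
  out <- kar[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read or write a unit table
#'
#' Tab-separated unit table with one row per chromosome unit and columns
#' `unit_id`, `swe_chrom`, `cat_chrom_1`, `cat_chrom_2`, `state_swe`,
#' `state_cat`, `state_reali`, `state_juvernica`, `class`, `is_sex`.
#' Missing fields (e.g. `cat_chrom_2` for a 1:1 unit) are written as `"."`.
#' Units with more than two CAT chromosomes store the extras in
#' `cat_chrom_2` joined by `";"`.
#'
#' @param path File path.
#' @return `read_unit_table()` returns a `karyotype`;
#'   `write_unit_table()` returns `path` invisibly.
#' @export
read_unit_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = ".")
  cat2 <- ifelse(is.na(df$cat_chrom_2), "", paste0(";", df$cat_chrom_2))
  units <- data.frame(
    unit_id = df$unit_id,
    swe_chrom = df$swe_chrom,
    cat_chroms = paste0(df$cat_chrom_1, cat2),
    state_swe = df$state_swe,
    state_cat = df$state_cat,
    state_reali = df$state_reali,
    state_juvernica = df$state_juvernica,
    is_sex = as.logical(df$is_sex),
    stringsAsFactors = FALSE
  )
  karyotype(units)
}

#' @rdname read_unit_table
#' @param kar A `karyotype`.
#' @export
write_unit_table <- function(kar, path) {
  parts <- strsplit(kar$cat_chroms, ";", fixed = TRUE)
  df <- data.frame(
    unit_id = kar$unit_id,
    swe_chrom = kar$swe_chrom,
    cat_chrom_1 = vapply(parts, `[`, "", 1L),
    cat_chrom_2 = vapply(parts, function(p) {
      if (length(p) > 1L) paste(p[-1L], collapse = ";") else "."
    }, ""),
    state_swe = kar$state_swe,
    state_cat = kar$state_cat,
    state_reali = kar$state_reali,
    state_juvernica = kar$state_juvernica,
    class = kar$class,
    is_sex = kar$is_sex,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
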