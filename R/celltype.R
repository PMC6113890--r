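#' Primary zones of a zonal expression profile
#'
#' Quantifies "expressed mainly in" a zone: a zone is primary when its
#' intensity is at least `detect_floor` (detected) and at least
#' `dominance_frac` of the profile's maximum intensity. Returns the empty
#' set when no zone is detected.
#'
#' @param intensities Numeric vector of length 4, ordered VZ, SVZ, IZ, CP
#'   (apical to pial); all values must be non-negative.
#' @param detect_floor Detection floor in intensity units.
#' @param dominance_frac Fraction of the maximum intensity a zone must reach
#'   to count as primary; in (0, 1].
#' @return Character vector of primary zone names (subset of VZ/SVZ/IZ/CP).
#' @examples
#' primary_zones(c(10, 1, 0, 0))        # "VZ"
#' primary_zones(c(8, 7, 0.5, 0.2))     # "VZ" "SVZ"  (bilaminar)
#' @export
primary_zones <- function(intensities, detect_floor = 0.5, dominance_frac = 0.5) {
  if (length(intensities) != 4L) {
    stop_ef("zonal profile must have 4 intensities (VZ, SVZ, IZ, CP)")
  }
  if (any(intensities < 0)) stop_ef("zone intensities must be non-negative")
  if (dominance_frac <= 0 || dominance_frac > 1) {
    stop_ef("dominance_frac must be in (0, 1]")
  }
  detected <- intensities >= detect_floor
  if (!any(detected)) return(character(0))
  keep <- detected & intensities >= dominance_frac * max(intensities)
  CORTICAL_ZONES[keep]
}

#' Classify one gene's cell type from enrichment and zones
#'
#' Decision table of the expression screen. Conflicted lineage probes
#' dominate everything (the gene is not cell-type-specific). Otherwise a
#' non-significant lineage contrast, or an undetected zonal profile, gives
#' `none`. GFP-minus-enriched genes expressed mainly in VZ are radial glial
#' progenitor (RGP) genes; GFP-plus-enriched genes are apical IP (VZ),
#' basal IP (SVZ), or bilaminar aIP+bIP (VZ+SVZ) genes; GFP-plus genes whose
#' zones reach the IZ or CP are neuron-class genes named by their earliest
#' (most apical) zone of expression, with a `PN-` prefix when the gene is
#' annotated as cortex-specific and its initial zone is IZ or CP. Any other
#' detected pattern is `mixed`.
#'
#' @param direction Lineage enrichment direction: `"up"` (GFP+), `"down"`
#'   (GFP-), or `"none"`.
#' @param significant Logical, lineage contrast significant.
#' @param conflicted Logical, probes significant in opposite directions.
#' @param zones Character vector from [primary_zones()].
#' @param cortex_specific Logical annotation (PN vs general neuron); from
#'   non-cortical expression data, not inferred here.
#' @return A single label from the closed vocabulary
#'   `r paste(CELLTYPE_LABELS, collapse = ", ")`.
#' @export
classify_cell_type <- function(direction, significant, conflicted, zones,
                               cortex_specific = FALSE) {
  unknown <- setdiff(zones, CORTICAL_ZONES)
  if (length(unknown)) stop_ef("unknown zone name(s): ", paste(unknown, collapse = ", "))
  if (isTRUE(conflicted)) return("conflicted")
  if (!isTRUE(significant) || direction == "none") return("none")
  if (length(zones) == 0L) return("none")
  zones <- CORTICAL_ZONES[CORTICAL_ZONES %in% zones]
  if (direction == "down") {
    if (identical(zones, "VZ")) return("RGP")
    return("mixed")
  }
  # direction == "up": GFP+ lineage
  if (identical(zones, "VZ")) return("aIP")
  if (identical(zones, "SVZ")) return("bIP")
  if (identical(zones, c("VZ", "SVZ"))) return("aIP+bIP")
  if (any(c("IZ", "CP") %in% zones)) {
    initial <- zones[1L]
    if (isTRUE(cortex_specific) && initial %in% c("IZ", "CP")) {
      return(paste0("PN-", tolower(initial)))
    }
    return(paste0("N-", tolower(initial)))
  }
  "mixed"
}

#' Classify all genes from a lineage summary and zonal profiles
#'
#' Table-level wrapper around [primary_zones()] and [classify_cell_type()].
#'
#' @param lineage Gene-level lineage summary from [lineage_enrichment()].
#' @param zonal Zonal profile table (`gene_id`, `VZ`, `SVZ`, `IZ`, `CP`).
#' @param annotations Optional data frame with `gene_id` and
#'   `cortex_specific`; genes absent from it default to not cortex-specific.
#' @param detect_floor,dominance_frac See [primary_zones()].
#' @return Data frame with `gene_id`, `label`, `direction`, `significant`,
#'   `conflicted`, `primary_zones` (comma-separated), `cortex_specific`.
#' @export
classify_cell_types <- function(lineage, zonal, annotations = NULL,
                                detect_floor = 0.5, dominance_frac = 0.5) {
  missing_zonal <- setdiff(lineage$gene_id, zonal$gene_id)
  if (length(missing_zonal)) {
    stop_ef("zonal profiles missing for gene(s): ",
            paste(head(missing_zonal, 5), collapse = ", "))
  }
  cs <- setNames(rep(FALSE, nrow(lineage)), lineage$gene_id)
  if (!is.null(annotations)) {
    hit <- intersect(annotations$gene_id, names(cs))
    cs[hit] <- annotations$cortex_specific[match(hit, annotations$gene_id)]
  }
  zi <- match(lineage$gene_id, zonal$gene_id)
  rows <- lapply(seq_len(nrow(lineage)), function(i) {
    prof <- as.numeric(zonal[zi[i], CORTICAL_ZONES])
    zones <- primary_zones(prof, detect_floor, dominance_frac)
    lab <- classify_cell_type(
      direction = lineage$direction[i],
      significant = lineage$significant[i],
      conflicted = lineage$conflicted[i],
      zones = zones,
      cortex_specific = cs[[lineage$gene_id[i]]]
    )
    data.frame(
      gene_id = lineage$gene_id[i], label = lab,
      direction = lineage$direction[i],
      significant = lineage$significant[i],
      conflicted = lineage$conflicted[i],
      primary_zones = paste(zones, collapse = ","),
      cortex_specific = cs[[lineage$gene_id[i]]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
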