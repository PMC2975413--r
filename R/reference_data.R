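# published reference segment table

#' Reference segment table from a sweet-potato starch micrograph
#'
#' Roundness values and GVF critical-point flags for the 15 watershed
#' segments of a published sweet-potato starch bright-field micrograph
#' containing 7 granules (segment 1 is the background). Feeding this table
#' through [flag_by_roundness()] and [classify_segments()] with the default
#' 0.70 roundness threshold reproduces the reference classification:
#' segments 2, 7, 8, 9, 10, 14 and 15 are the granules.
#'
#' @return data frame with columns `segment`, `roundness`, `critical_point`
#'   (logical), `is_background` (logical).
#' @export
reference_segment_table <- function() {
  utils::read.csv(system.file("extdata", "reference_segments.csv",
                              package = "starchseg"))
}

#' Classify a (roundness, critical-point) segment table
#'
#' Applies the two-criterion decision rule to a table of precomputed
#' roundness values and critical-point flags (background rows excluded
#' first): roundness below the threshold, or no critical point, means
#' oversegment; otherwise the segment is a core granule.
#'
#' @param table data frame like [reference_segment_table()].
#' @param threshold roundness cut-off.
#' @return the non-background rows with a `classification` column.
#' @export
classify_segment_table <- function(table, threshold = 0.70) {
  tab <- table[!table$is_background, , drop = FALSE]
  records <- data.frame(label = tab$segment, roundness = tab$roundness,
                        has_critical_point = "not_evaluated",
                        classification = "pending",
                        stringsAsFactors = FALSE)
  records <- flag_by_roundness(records, threshold = threshold)
  classify_segments(records,
                    data.frame(label = tab$segment,
                               found = tab$critical_point))
}
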