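# Dual-barcoded sequencing templates. Every molecule in the library is
#   A + FwdBarcode + FwdPrimer + insert + RC(RevPrimer) + RC(RevBarcode) + A
# with single literal A bases flanking the construct.

#' Build one dual-barcoded template
#'
#' All components must be concrete DNA (no IUPAC degeneracies left): the
#' primer sequences embedded here are realizations, either the genomic
#' bases at the binding site or a random disambiguation of the primer
#' oligo (see [assign_templates()]).
#'
#' @param insert Primer-exclusive insert (the ASV).
#' @param fwd_barcode,rev_barcode Barcode pair for the sample.
#' @param fwd_primer,rev_primer Concrete primer realizations.
#' @return A one-row tibble with `seq` and the structure spans
#'   (`span_start`/`span_end` list-columns naming each segment; 0-based
#'   half-open, tiling the sequence exactly).
#' @export
build_template <- function(insert, fwd_barcode, rev_barcode,
                           fwd_primer, rev_primer) {
  parts <- c(lead_a = "A", fwd_barcode = toupper(fwd_barcode),
             fwd_primer = toupper(fwd_primer), insert = toupper(insert),
             rc_rev_primer = reverse_complement(toupper(rev_primer)),
             rc_rev_barcode = reverse_complement(toupper(rev_barcode)),
             trail_a = "A")
  if (any(!nzchar(parts))) {
    stop("all template components must be non-empty", call. = FALSE)
  }
  concrete <- grepl("^[ACGT]+$", parts)
  if (!all(concrete)) {
    stop(sprintf("degenerate bases remain in component(s): %s",
                 paste(names(parts)[!concrete], collapse = ", ")),
         call. = FALSE)
  }
  ends <- cumsum(nchar(parts))
  starts <- ends - nchar(parts)
  tibble::tibble(
    seq = paste(parts, collapse = ""),
    spans = list(tibble::tibble(segment = names(parts),
                                start = unname(starts),
                                end = unname(ends)))
  )
}

#' Assign barcoded templates to every sample x ASV with positive count
#'
#' For each sample and each ASV with count c > 0 one template is built and
#' carried with multiplicity c, so total multiplicity per sample equals
#' that sample's depth.
#'
#' In `"oligo"` primer mode (the default) degenerate primer positions are
#' realized as a random concrete disambiguation of the primer oligo, as in
#' a real library where the amplicon 5' ends carry the synthetic primer; in
#' `"genomic"` mode the bases found at the binding site are kept.
#'
#' @param counts Count tibble from [simulate_counts()] (columns `asv_id`,
#'   `sample_id`, `count`).
#' @param catalog ASV catalog from [asv_catalog()].
#' @param barcodes Barcode tibble (`sample_id`, `fwd_barcode`,
#'   `rev_barcode`); every sample in `counts` must have a pair.
#' @param fwd_primer,rev_primer IUPAC primer strings (used in oligo mode).
#' @param primer_mode `"oligo"` or `"genomic"`.
#' @param seed Integer seed (for oligo-mode disambiguation).
#' @return Tibble with `template_id`, `sample_id`, `genome_id`, `asv_id`,
#'   `seq`, `copies`.
#' @export
assign_templates <- function(counts, catalog, barcodes,
                             fwd_primer, rev_primer,
                             primer_mode = c("oligo", "genomic"),
                             seed = 1L) {
  primer_mode <- match.arg(primer_mode)
  stopifnot(all(c("asv_id", "sample_id", "count") %in% names(counts)))
  barcodes <- validate_barcodes(barcodes)
  missing <- setdiff(unique(counts$sample_id), barcodes$sample_id)
  if (length(missing) > 0) {
    stop(sprintf("no barcode pair for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  f_len <- nchar(fwd_primer); r_len <- nchar(rev_primer)
  pos <- counts[counts$count > 0, ]
  empty <- setdiff(unique(counts$sample_id), unique(pos$sample_id))
  if (length(empty) > 0) {
    warning(sprintf("sample(s) with all-zero counts yield no templates: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  if (nrow(pos) == 0) {
    return(tibble::tibble(template_id = character(0), sample_id = character(0),
                          genome_id = character(0), asv_id = character(0),
                          seq = character(0), copies = integer(0)))
  }
  pos <- dplyr::inner_join(
    pos[, c("asv_id", "sample_id", "count")],
    catalog[, c("asv_id", "genome_id", "insert_seq", "product_seq")],
    by = "asv_id"
  )
  pos <- dplyr::inner_join(pos, barcodes, by = "sample_id")
  pos <- dplyr::arrange(pos, .data$sample_id, .data$asv_id)
  .with_seed(.substream(seed, "templates"), {
    seqs <- vapply(seq_len(nrow(pos)), function(i) {
      if (primer_mode == "oligo") {
        fp <- realize_iupac(fwd_primer)
        rp <- realize_iupac(rev_primer)
      } else {
        prod <- pos$product_seq[[i]]
        fp <- substr(prod, 1, f_len)
        rp <- reverse_complement(substr(prod, nchar(prod) - r_len + 1,
                                        nchar(prod)))
      }
      build_template(pos$insert_seq[[i]], pos$fwd_barcode[[i]],
                     pos$rev_barcode[[i]], fp, rp)$seq
    }, character(1))
    tibble::tibble(
      template_id = sprintf("%s_%s", pos$sample_id, pos$asv_id),
      sample_id = pos$sample_id,
      genome_id = pos$genome_id,
      asv_id = pos$asv_id,
      seq = seqs,
      copies = as.integer(pos$count)
    )
  })
}
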