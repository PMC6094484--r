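# Novelty class codes, lncRNA typing (ancRNA / lincRNA), sense-antisense
# pairing and neighbor genomic context.

.tx_exons <- function(ann, id) {
  ann$exons[ann$exons$transcript_id == id, c("start", "end"), drop = FALSE]
}

.tx_junctions <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(character(0))
  paste(ex$end[-n], ex$start[-1], sep = "-")
}

# gene loci (union span over each gene's transcripts)
gene_loci <- function(ann) {
  sp <- tx_spans(ann)
  start <- tapply(sp$start, sp$gene_id, min)
  end <- tapply(sp$end, sp$gene_id, max)
  g <- data.frame(gene_id = names(start),
                  chrom = sp$chrom[match(names(start), sp$gene_id)],
                  strand = sp$strand[match(names(start), sp$gene_id)],
                  start = as.integer(start), end = as.integer(end),
                  coding = as.logical(tapply(sp$biotype == "coding",
                                             sp$gene_id, any)),
                  stringsAsFactors = FALSE)
  rownames(g) <- NULL
  g[order(g$chrom, g$start), ]
}

#' Assign novelty class codes to assembled transcripts
#'
#' Each assembled transcript is compared with the reference annotation and
#' tagged with one class code, by precedence `=` > `J` > `X` > `P` > `U`:
#' \describe{
#'   \item{`=`}{exon chain identical to a reference transcript (same strand).}
#'   \item{`J`}{shares at least one internal splice junction with a
#'     same-strand reference transcript but has a different chain.}
#'   \item{`X`}{at least 1 bp of exonic overlap with a reference transcript
#'     on the opposite strand.}
#'   \item{`P`}{same strand, no exonic overlap with any same-strand reference
#'     transcript, and its 5' end lies within `tandem_window` bp downstream
#'     of a reference transcript's 3' end.}
#'   \item{`U`}{its locus overlaps no reference gene locus on either strand.}
#'   \item{`other`}{anything else.}
#' }
#'
#' @param assembled,reference [genome_annotation()] objects sharing a
#'   chromosome namespace.
#' @param tandem_window run-on window for class `P` (bp, default 2000).
#' @return named character vector of class codes, one per assembled
#'   transcript.
#' @export
assign_class_codes <- function(assembled, reference, tandem_window = 2000L) {
  if (!all(assembled$transcripts$chrom %in% names(reference$chrom_lengths)))
    stop("assembled transcript on chromosome unknown to the reference")
  ref_sp <- tx_spans(reference)
  ref_ex <- split(reference$exons[, c("start", "end")],
                  reference$exons$transcript_id)
  ref_chain <- vapply(ref_sp$transcript_id, function(id) {
    ex <- ref_ex[[id]]
    paste(ex$start, ex$end, sep = ":", collapse = ";")
  }, character(1))
  ref_junc <- lapply(ref_sp$transcript_id, function(id) .tx_junctions(ref_ex[[id]]))
  names(ref_junc) <- ref_sp$transcript_id
  genes <- gene_loci(reference)
  q_sp <- tx_spans(assembled)
  q_ex <- split(assembled$exons[, c("start", "end")],
                assembled$exons$transcript_id)

  codes <- vapply(seq_len(nrow(q_sp)), function(i) {
    qi <- q_sp[i, ]
    ex_q <- q_ex[[qi$transcript_id]]
    same_chr <- ref_sp$chrom == qi$chrom
    cand <- which(same_chr & ref_sp$start < qi$end & ref_sp$end > qi$start)
    same_str <- cand[ref_sp$strand[cand] == qi$strand]
    opp_str <- cand[ref_sp$strand[cand] != qi$strand]
    q_chain <- paste(ex_q$start, ex_q$end, sep = ":", collapse = ";")
    # "="
    if (any(ref_chain[same_str] == q_chain)) return("=")
    # J: shared internal junction, same strand, different chain
    qj <- .tx_junctions(ex_q)
    if (length(qj) > 0L) {
      for (r in same_str)
        if (length(intersect(qj, ref_junc[[ref_sp$transcript_id[r]]])) > 0L)
          return("J")
    } else {
      # a mono-exon query shares no junction; same-strand multi-exon refs
      # cannot make it J
    }
    # X: exonic overlap on the opposite strand
    for (r in opp_str)
      if (exonic_overlap_bp(ex_q, ref_ex[[ref_sp$transcript_id[r]]]) > 0L)
        return("X")
    # P: same strand, no exonic overlap, 5' end within the tandem window
    #    downstream of a reference 3' end
    exonic_same <- any(vapply(same_str, function(r)
      exonic_overlap_bp(ex_q, ref_ex[[ref_sp$transcript_id[r]]]) > 0L,
      logical(1)))
    if (!exonic_same) {
      same_all <- which(same_chr & ref_sp$strand == qi$strand)
      for (r in same_all) {
        d <- if (qi$strand == "+") qi$start - ref_sp$end[r]
             else ref_sp$start[r] - qi$end
        if (d >= 0L && d <= tandem_window) return("P")
      }
    }
    # U: no gene-locus overlap on either strand
    gcand <- genes$chrom == qi$chrom & genes$start < qi$end & genes$end > qi$start
    if (!any(gcand)) return("U")
    "other"
  }, character(1))
  setNames(codes, q_sp$transcript_id)
}

#' Exonic antisense overlap of a transcript with coding reference transcripts
#'
#' @return total exonic overlap (bp) with the single best opposite-strand
#'   coding reference transcript, plus that transcript's id.
#' @keywords internal
.best_antisense_overlap <- function(tx_id, assembled, reference) {
  sp <- tx_spans(assembled)
  qi <- sp[sp$transcript_id == tx_id, ]
  ex_q <- .tx_exons(assembled, tx_id)
  ref_sp <- tx_spans(reference)
  cand <- which(ref_sp$chrom == qi$chrom & ref_sp$strand != qi$strand &
                  ref_sp$biotype == "coding" &
                  ref_sp$start < qi$end & ref_sp$end > qi$start)
  if (length(cand) == 0L) return(list(bp = 0L, ref = NA_character_))
  ov <- vapply(cand, function(r)
    exonic_overlap_bp(ex_q, .tx_exons(reference, ref_sp$transcript_id[r])),
    integer(1))
  best <- which.max(ov)
  list(bp = ov[best], ref = ref_sp$transcript_id[cand[best]])
}

#' Type lncRNAs as antisense (ancRNA) or intergenic (lincRNA)
#'
#' A transcript is an ancRNA iff its exonic antisense overlap with some
#' coding reference transcript exceeds 100 bp (strictly); otherwise it is a
#' lincRNA.
#'
#' @param lnc_ids lncRNA transcript ids (rows of `assembled`).
#' @param assembled annotation containing the lncRNAs.
#' @param reference reference annotation.
#' @param min_overlap exonic antisense overlap (bp) strictly required for the
#'   ancRNA call (default 100).
#' @return named character vector, `"ancRNA"` or `"lincRNA"`.
#' @export
classify_lncrna_type <- function(lnc_ids, assembled, reference,
                                 min_overlap = 100L) {
  vapply(lnc_ids, function(id) {
    b <- .best_antisense_overlap(id, assembled, reference)
    if (b$bp > min_overlap) "ancRNA" else "lincRNA"
  }, character(1))
}

#' Form sense mRNA / antisense lncRNA pairs
#'
#' One pair is emitted per (mRNA, ancRNA) combination with exonic antisense
#' overlap strictly greater than `min_overlap` bp. Orientation is
#' `full_overlap` when either transcript's span nests inside the other's,
#' `head_overlap` when the two 5' ends fall in the shared region and
#' `tail_overlap` when the two 3' ends do (ends resolved per strand).
#'
#' @param anc_ids ancRNA transcript ids.
#' @param assembled annotation containing the ancRNAs.
#' @param reference reference annotation (coding transcripts are the mRNAs).
#' @param min_overlap bp threshold (default 100, strict).
#' @return data.frame with `mrna_id`, `ancrna_id`, `overlap_bp`,
#'   `orientation`.
#' @export
pair_sense_antisense <- function(anc_ids, assembled, reference,
                                 min_overlap = 100L) {
  sp_a <- tx_spans(assembled)
  sp_r <- tx_spans(reference)
  out <- list()
  for (id in anc_ids) {
    qi <- sp_a[sp_a$transcript_id == id, ]
    ex_q <- .tx_exons(assembled, id)
    cand <- which(sp_r$chrom == qi$chrom & sp_r$strand != qi$strand &
                    sp_r$biotype == "coding" &
                    sp_r$start < qi$end & sp_r$end > qi$start)
    for (r in cand) {
      rid <- sp_r$transcript_id[r]
      bp <- exonic_overlap_bp(ex_q, .tx_exons(reference, rid))
      if (bp <= min_overlap) next
      orientation <- .pair_orientation(qi$start, qi$end, qi$strand,
                                       sp_r$start[r], sp_r$end[r],
                                       sp_r$strand[r])
      out[[length(out) + 1L]] <- data.frame(
        mrna_id = rid, ancrna_id = id, overlap_bp = bp,
        orientation = orientation, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(mrna_id = character(0), ancrna_id = character(0),
                      overlap_bp = integer(0), orientation = character(0)))
  do.call(rbind, out)
}

# last-base positions of the 5' and 3' ends of a span (0-based)
.ends_of <- function(start, end, strand) {
  if (strand == "+") c(p5 = start, p3 = end - 1L)
  else c(p5 = end - 1L, p3 = start)
}

.pair_orientation <- function(a_start, a_end, a_strand,
                              b_start, b_end, b_strand) {
  if ((a_start >= b_start && a_end <= b_end) ||
      (b_start >= a_start && b_end <= a_end)) return("full_overlap")
  ea <- .ends_of(a_start, a_end, a_strand)
  eb <- .ends_of(b_start, b_end, b_strand)
  in_b <- function(p) p >= b_start && p < b_end
  in_a <- function(p) p >= a_start && p < a_end
  if (in_b(ea["p5"]) && in_a(eb["p5"])) return("head_overlap")
  if (in_b(ea["p3"]) && in_a(eb["p3"])) return("tail_overlap")
  NA_character_
}

#' Neighbor genomic context of a lncRNA
#'
#' Reports every reference gene whose locus lies within `max_gap` bp of the
#' lncRNA locus. Relative to the lncRNA's transcription direction: a gene on
#' its 5' side on the opposite strand is `divergent` (the two 5' ends face
#' each other), a gene on its 3' side on the opposite strand is `convergent`
#' (3' ends face each other), and a gene on its 5' side on the same strand
#' is `tandem_upstream`. Same-strand downstream genes carry no relation and
#' are omitted. `gap_bp` is the locus-to-locus distance (0 if overlapping).
#'
#' @param lnc_id lncRNA transcript id.
#' @param assembled annotation containing the lncRNA.
#' @param reference reference annotation.
#' @param max_gap maximum gap (bp, default 1000).
#' @return data.frame with `lnc_id`, `gene_id`, `relation`, `gap_bp`.
#' @export
neighbor_context <- function(lnc_id, assembled, reference, max_gap = 1000L) {
  sp <- tx_spans(assembled)
  qi <- sp[sp$transcript_id == lnc_id, ]
  genes <- gene_loci(reference)
  genes <- genes[genes$chrom == qi$chrom, , drop = FALSE]
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      relation = character(0), gap_bp = integer(0))
  if (nrow(genes) == 0L) return(empty)
  gap <- pmax(pmax(genes$start - qi$end, qi$start - genes$end), 0L)
  genes <- genes[gap <= max_gap, , drop = FALSE]
  gap <- gap[gap <= max_gap]
  if (nrow(genes) == 0L) return(empty)
  # side of the gene relative to the lncRNA's 5'->3' direction
  left_of <- ifelse(genes$end <= qi$start, TRUE,
                    ifelse(genes$start >= qi$end, FALSE,
                           (genes$start + genes$end) < (qi$start + qi$end)))
  on_5p_side <- if (qi$strand == "+") left_of else !left_of
  opp <- genes$strand != qi$strand
  relation <- ifelse(opp & on_5p_side, "divergent",
                     ifelse(opp & !on_5p_side, "convergent",
                            ifelse(!opp & on_5p_side, "tandem_upstream",
                                   NA_character_)))
  keep <- !is.na(relation)
  if (!any(keep)) return(empty)
  data.frame(lnc_id = lnc_id, gene_id = genes$gene_id[keep],
             relation = relation[keep], gap_bp = as.integer(gap[keep]),
             stringsAsFactors = FALSE)
}
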