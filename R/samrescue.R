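# Multi-mapped read rescue for tagged alignments.
#
# Alignments arrive from the aligner with a MAPQ encoding the number of
# mapping locations (255 unique, 3 dual, 1 triple/quadruple, 0 five-plus),
# an AS alignment score, an XF category (CODING/UTR/INTRONIC/INTERGENIC), a
# GE gene tag for stranded exonic overlap, and XC/XM cell and molecular
# barcodes. The rescue rules decide which multi-mapped reads may contribute
# a "primary" alignment to digital gene expression counting.

is_exonic <- function(xf) xf %in% c("CODING", "UTR")

#' Read a tagged SAM/BAM file of alignments
#'
#' Extracts the fields the rescue rules operate on, preserving record order
#' (which is the documented tie-break order for co-maximal alignments).
#'
#' @param path SAM or BAM file with AS/XF/GE/XC/XM tags.
#' @return data.frame with columns `read_id`, `mapq`, `as_score`, `xf`,
#'   `ge`, `xc`, `xm`, `primary` (from the 0x100 secondary flag).
#' @export
read_tagged_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  } else path
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "mapq"),
      tag = c("AS", "XF", "GE", "XC", "XM")))[[1]]
  data.frame(read_id = res$qname,
             mapq = as.integer(res$mapq),
             as_score = as.integer(res$tag$AS),
             xf = as.character(res$tag$XF),
             ge = as.character(res$tag$GE),
             xc = as.character(res$tag$XC),
             xm = as.character(res$tag$XM),
             primary = bitwAnd(res$flag, 256L) == 0L,
             stringsAsFactors = FALSE)
}

#' Is an alignment set eligible for multi-mapper rescue?
#'
#' A set fails when it has more than four alignments (MAPQ 0, never rescued)
#' or when any CODING/UTR alignment lacks a GE gene tag.
#'
#' @param aset data.frame of alignments for one read (columns as in
#'   [read_tagged_sam()]).
#' @return Logical scalar.
#' @export
rescue_eligibility <- function(aset) {
  if (nrow(aset) > 4) return(FALSE)
  !any(is_exonic(aset$xf) & is.na(aset$ge))
}

#' Apply the rescue rules to one read's alignment set
#'
#' A single alignment (unique mapper) passes through unchanged. For 2-4
#' alignments, exactly one alignment becomes primary iff (a) the set is
#' eligible, (b) no two alignments carry different GE genes, and (c) an
#' exonic alignment attains the (co-)maximal alignment score — i.e. all other
#' alignments are intronic/intergenic or exonic for the same gene with no
#' higher score. Co-maximal exonic ties break by input order. If the criteria
#' fail, ALL alignments are flagged secondary.
#'
#' @param aset data.frame of alignments sharing one `read_id`.
#' @return The data.frame with the `primary` column re-assigned.
#' @export
rescue <- function(aset) {
  if (nrow(aset) == 0) stop("empty alignment set")
  if (length(unique(aset$read_id)) != 1) {
    stop("alignment set mixes read ids: ",
         paste(unique(aset$read_id), collapse = ", "))
  }
  if (nrow(aset) == 1) return(aset)
  aset$primary <- FALSE
  if (!rescue_eligibility(aset)) return(aset)
  genes <- unique(aset$ge[!is.na(aset$ge)])
  if (length(genes) > 1) return(aset)          # cross-gene sets disallowed
  exonic <- is_exonic(aset$xf)
  co_max <- aset$as_score == max(aset$as_score)
  allowed <- which(exonic & co_max)
  if (length(allowed) == 0) return(aset)       # best score is non-exonic
  aset$primary[allowed[1]] <- TRUE             # input-order tie-break
  aset
}

#' Apply rescue to a whole alignment table
#'
#' Groups by `read_id` (contiguous records assumed, as produced by the
#' aligner) and applies [rescue()] to each group, preserving record order.
#'
#' @param alignments data.frame as from [read_tagged_sam()].
#' @return data.frame with `primary` re-assigned per read.
#' @export
rescue_reads <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  groups <- split(seq_len(nrow(alignments)), alignments$read_id)
  for (ix in groups) {
    alignments[ix, ] <- rescue(alignments[ix, , drop = FALSE])
  }
  alignments
}

#' Digital gene expression from rescued alignments
#'
#' Counts primary alignments with `mapq >= readmq`, collapsing duplicate
#' (cell barcode, molecular barcode, gene) triples to one molecule. The
#' default `readmq = 1` admits rescued dual/triple/quadruple mappers; the
#' conservative unique-only convention is `readmq = 10` (only MAPQ 255
#' survives). Records missing a barcode or gene are skipped with one
#' warning carrying the skip count.
#'
#' @param alignments data.frame with `primary` already assigned (e.g. via
#'   [rescue_reads()]).
#' @param readmq Minimum MAPQ for inclusion.
#' @return Integer gene x cell count matrix.
#' @export
count_dge <- function(alignments, readmq = 1) {
  keep <- alignments$primary & alignments$mapq >= readmq
  a <- alignments[keep, , drop = FALSE]
  bad <- is.na(a$ge) | is.na(a$xc) | is.na(a$xm)
  if (any(bad)) {
    warning("skipping ", sum(bad),
            " primary alignment(s) without gene or barcode tags")
    a <- a[!bad, , drop = FALSE]
  }
  if (nrow(a) == 0) {
    return(matrix(0L, 0, 0, dimnames = list(NULL, NULL)))
  }
  umis <- unique(a[, c("xc", "xm", "ge")])
  tt <- table(factor(umis$ge), factor(umis$xc))
  m <- matrix(as.integer(tt), nrow = nrow(tt),
              dimnames = list(gene = rownames(tt), cell = colnames(tt)))
  m
}

#' Write tagged alignments as a SAM file
#'
#' Emits a minimal single-reference SAM with AS/XF/GE/XC/XM tags, suitable
#' for generating synthetic fixtures that exercise every rescue rule branch.
#' Records are written in row order with increasing positions so that
#' round-trips preserve order.
#'
#' @param alignments data.frame with columns `read_id`, `mapq`, `as_score`,
#'   `xf`, `ge` (NA = no tag), `xc`, `xm`, and optionally `primary`
#'   (default: first record of each read).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_tagged_sam <- function(alignments, path) {
  a <- alignments
  if (is.null(a$primary)) {
    a$primary <- !duplicated(a$read_id)
  }
  n <- nrow(a)
  seq <- strrep("A", 20)
  qual <- strrep("I", 20)
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:chr1\tLN:%d", 1000 + 100 * n))
  for (i in seq_len(n)) {
    flag <- if (a$primary[i]) 0L else 256L
    tags <- sprintf("AS:i:%d\tXF:Z:%s", a$as_score[i], a$xf[i])
    if (!is.na(a$ge[i])) tags <- paste0(tags, sprintf("\tGE:Z:%s", a$ge[i]))
    tags <- paste0(tags, sprintf("\tXC:Z:%s\tXM:Z:%s", a$xc[i], a$xm[i]))
    lines <- c(lines, sprintf("%s\t%d\tchr1\t%d\t%d\t20M\t*\t0\t0\t%s\t%s\t%s",
                              a$read_id[i], flag, 100 * i, a$mapq[i],
                              seq, qual, tags))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic alignment fixture covering every rescue rule branch
#'
#' Twelve reads: unique mappers, a rescuable dual (exonic max over intronic),
#' a cross-gene dual, an intronic-dominant dual, a same-gene co-max dual, a
#' CODING-without-GE dual, a rescuable triple and quadruple, a five-way
#' mapper (never rescued), and UMI duplicates for the collapse contract.
#'
#' @return data.frame of tagged alignments (one row per alignment).
#' @export
demo_rescue_alignments <- function() {
  al <- function(read_id, mapq, as_score, xf, ge, xc, xm) {
    data.frame(read_id = read_id, mapq = mapq, as_score = as_score,
               xf = xf, ge = ge, xc = xc, xm = xm,
               stringsAsFactors = FALSE)
  }
  rbind(
    # r01, r02: unique mappers, geneA in two different cells
    al("r01", 255L, 50L, "CODING", "geneA", "CELL1", "U01"),
    al("r02", 255L, 55L, "UTR", "geneA", "CELL2", "U02"),
    # r03: rescuable dual -- exonic max beats intronic
    al("r03", 3L, 50L, "CODING", "geneB", "CELL1", "U03"),
    al("r03", 3L, 40L, "INTRONIC", NA, "CELL1", "U03"),
    # r04: dual to two different genes -> all secondary
    al("r04", 3L, 50L, "CODING", "geneA", "CELL1", "U04"),
    al("r04", 3L, 50L, "CODING", "geneB", "CELL1", "U04"),
    # r05: intronic outscores exonic -> all secondary
    al("r05", 3L, 60L, "INTRONIC", NA, "CELL1", "U05"),
    al("r05", 3L, 50L, "CODING", "geneB", "CELL1", "U05"),
    # r06: same-gene co-max exonic dual -> first is primary
    al("r06", 3L, 50L, "CODING", "geneC", "CELL2", "U06"),
    al("r06", 3L, 50L, "UTR", "geneC", "CELL2", "U06"),
    # r07: CODING without GE -> ineligible
    al("r07", 3L, 50L, "CODING", NA, "CELL2", "U07"),
    al("r07", 3L, 40L, "INTERGENIC", NA, "CELL2", "U07"),
    # r08: rescuable triple (exonic max, others non-coding)
    al("r08", 1L, 50L, "CODING", "geneB", "CELL2", "U08"),
    al("r08", 1L, 45L, "INTRONIC", NA, "CELL2", "U08"),
    al("r08", 1L, 40L, "INTERGENIC", NA, "CELL2", "U08"),
    # r09: rescuable quadruple (co-max exonic same gene + non-coding)
    al("r09", 1L, 50L, "CODING", "geneA", "CELL1", "U09"),
    al("r09", 1L, 50L, "CODING", "geneA", "CELL1", "U09"),
    al("r09", 1L, 40L, "INTRONIC", NA, "CELL1", "U09"),
    al("r09", 1L, 30L, "INTERGENIC", NA, "CELL1", "U09"),
    # r10: five alignments (MAPQ 0) -> never rescued
    al("r10", 0L, 50L, "CODING", "geneC", "CELL1", "U10"),
    al("r10", 0L, 50L, "CODING", "geneC", "CELL1", "U10"),
    al("r10", 0L, 40L, "INTRONIC", NA, "CELL1", "U10"),
    al("r10", 0L, 40L, "INTRONIC", NA, "CELL1", "U10"),
    al("r10", 0L, 30L, "INTERGENIC", NA, "CELL1", "U10"),
    # r11, r12: unique mappers duplicating r01's (cell, UMI, gene) molecule
    al("r11", 255L, 50L, "CODING", "geneA", "CELL1", "U01"),
    al("r12", 255L, 50L, "CODING", "geneA", "CELL1", "U12")
  )
}
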