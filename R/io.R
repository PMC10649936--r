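# Readers/writers for the external formats the pipeline touches
# (FASTA, GFF3, Newick, TSV tables), plus exon-intron summarization.

#' Read a protein FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' Sequences are upper-cased and trailing stop characters ('*') are stripped.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{AAStringSet}.
#' @export
readProteome <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(sub("\\*+$", "", as.character(x)))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty))
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  bad <- vapply(seqs, function(s)
    length(setdiff(unique(strsplit(s, "")[[1]]), c(.AA20, "X"))) > 0, logical(1))
  if (any(bad))
    stop("invalid residue letters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a protein FASTA file
#'
#' @param proteome Named \code{AAStringSet} or character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  if (is.character(proteome))
    proteome <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(proteome, path)
  invisible(path)
}

#' Read gene loci (with exons) from a GFF3 file
#'
#' Genes get an ordinal \code{rank} (0-based) per chromosome by ascending
#' start, ties broken by gene id. Exons are attached per gene and clipped to
#' the gene body with a warning when they stick out.
#'
#' @param path Path to a GFF3 file with \code{gene} and \code{exon} features.
#' @return A \code{GRanges} (1-based, closed intervals, the GFF3/Bioconductor
#'   convention) with metadata columns \code{gene_id}, \code{rank},
#'   \code{n_exons} and an \code{IRangesList} column \code{exons}.
#' @export
readGeneLoci <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body)) {
    warning("no features in ", path)
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character()
    return(gr)
  }
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("malformed GFF3 line ", i, ": fewer than 9 columns", call. = FALSE)
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e))
      stop("malformed coordinates at line ", i, call. = FALSE)
    if (e < s)
      stop("feature end < start at line ", i, call. = FALSE)
  }
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[tolower(gff$type) == "gene"]
  exons <- gff[tolower(gff$type) == "exon"]
  gid <- genes$ID
  if (is.null(gid) || anyNA(gid)) gid <- names(genes)
  if (is.null(gid)) stop("gene features need ID attributes", call. = FALSE)

  # ranks per chromosome: ascending start, ties by gene_id
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes), gid)
  genes <- genes[ord]; gid <- gid[ord]
  rk <- unlist(lapply(split(seq_along(genes),
                            as.character(GenomicRanges::seqnames(genes))),
                      function(i) seq_along(i) - 1L), use.names = FALSE)
  # split() reorders by chromosome name, but genes are already sorted that way

  exl <- rep(list(IRanges::IRanges()), length(genes))
  names(exl) <- gid
  if (length(exons)) {
    parent <- vapply(exons$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
    keep <- parent %in% gid
    exons <- exons[keep]; parent <- parent[keep]
    for (i in seq_along(exons)) {
      g <- match(parent[i], gid)
      es <- GenomicRanges::start(exons)[i]; ee <- GenomicRanges::end(exons)[i]
      gs <- GenomicRanges::start(genes)[g]; ge <- GenomicRanges::end(genes)[g]
      if (es < gs || ee > ge) {
        warning("exon outside gene ", gid[g], "; clipped")
        es <- max(es, gs); ee <- min(ee, ge)
      }
      exl[[g]] <- c(exl[[g]], IRanges::IRanges(es, ee))
    }
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(GenomicRanges::start(genes),
                              GenomicRanges::end(genes)),
    strand = GenomicRanges::strand(genes))
  S4Vectors::mcols(out)$gene_id <- gid
  S4Vectors::mcols(out)$rank <- rk
  S4Vectors::mcols(out)$n_exons <- lengths(exl)
  S4Vectors::mcols(out)$exons <- IRanges::IRangesList(exl)
  names(out) <- gid
  out
}

#' Write gene loci as GFF3
#'
#' @param loci \code{GRanges} as returned by \code{\link{readGeneLoci}} (or
#'   the synthetic generator).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGeneLoci <- function(loci, path) {
  gid <- loci$gene_id
  feats <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(loci),
    ranges = IRanges::ranges(loci),
    strand = GenomicRanges::strand(loci),
    type = "gene", ID = gid, source = "rbgminer")
  exl <- loci$exons
  if (!is.null(exl)) {
    nex <- lengths(exl)
    if (sum(nex)) {
      flat <- unlist(exl, use.names = FALSE)
      parent <- rep(gid, nex)
      ex <- GenomicRanges::GRanges(
        seqnames = rep(GenomicRanges::seqnames(loci), nex),
        ranges = flat,
        strand = rep(GenomicRanges::strand(loci), nex),
        type = "exon",
        ID = paste0(parent, ".exon", unlist(lapply(nex[nex > 0], seq_len))),
        source = "rbgminer")
      ex$Parent <- as(parent, "CharacterList")
      feats$Parent <- as(rep(list(character()), length(feats)), "CharacterList")
      feats <- c(feats, ex)
    }
  }
  feats <- feats[order(as.character(GenomicRanges::seqnames(feats)),
                       GenomicRanges::start(feats),
                       feats$type != "gene", feats$ID)]
  rtracklayer::export(feats, path, format = "gff3")
  invisible(path)
}

#' Count introns per gene
#'
#' Intron count is \code{max(0, n_exons - 1)}; genes without annotated exons
#' get 0 with a warning.
#'
#' @param loci \code{GRanges} from \code{\link{readGeneLoci}}.
#' @return data.frame with columns \code{gene_id}, \code{n_exons},
#'   \code{introns}.
#' @export
intronCounts <- function(loci) {
  n <- loci$n_exons
  noex <- loci$gene_id[n == 0L]
  if (length(noex))
    warning("gene(s) without exon features (intron count set to 0): ",
            paste(noex, collapse = ", "))
  data.frame(gene_id = loci$gene_id, n_exons = n,
             introns = pmax(0L, n - 1L), row.names = NULL)
}

#' Read a protein-domain hit table
#'
#' Accepts either the package's minimal 6-column whitespace/tab-delimited
#' layout (\code{protein_id model_name model_length ali_from ali_to e_value})
#' or an hmmscan \code{--domtblout} file (space-aligned, \code{#} comments);
#' for the latter, model coordinates are taken from the \code{hmm from/to}
#' columns and the independent domain E-value is used.
#'
#' @param path Path to the table.
#' @return data.frame with columns \code{protein_id}, \code{model_name},
#'   \code{model_length}, \code{ali_from}, \code{ali_to}, \code{e_value}.
#' @export
readDomainTable <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) >= 19) {        # hmmscan domtblout: target model, query protein
      vals <- c(f[4], f[1], f[3], f[16], f[17], f[13])
    } else if (length(f) == 6) {  # minimal layout
      vals <- f
    } else {
      stop("domain table line ", i, ": expected 6 columns (or domtblout)",
           call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(vals[3:6]))
    if (anyNA(num))
      stop("malformed numeric field at line ", i, call. = FALSE)
    data.frame(protein_id = vals[1], model_name = vals[2],
               model_length = num[1], ali_from = num[2], ali_to = num[3],
               e_value = num[4])
  })
  out <- do.call(rbind, c(rows,
    list(data.frame(protein_id = character(), model_name = character(),
                    model_length = numeric(), ali_from = numeric(),
                    ali_to = numeric(), e_value = numeric()))))
  bad <- which(out$model_length <= 0 | out$ali_from < 1 |
               out$ali_to < out$ali_from | out$ali_to > out$model_length |
               out$e_value < 0)
  if (length(bad))
    stop("domain table row(s) violate coordinate/E-value invariants: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out
}

#' Read a replicate qPCR Ct table
#'
#' Expected tab-delimited columns: \code{gene}, \code{sample},
#' \code{replicate}, \code{ct_target}, \code{ct_reference}.
#'
#' @param path Path to the TSV.
#' @return data.frame with the columns above.
#' @export
readCtTable <- function(path) {
  stopifnot(file.exists(path))
  ct <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "sample", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cc in c("ct_target", "ct_reference")) {
    v <- ct[[cc]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("Ct values in '", cc, "' must be finite and positive", call. = FALSE)
  }
  ct[need]
}

#' Newick tree I/O
#'
#' Thin wrappers around \code{ape::read.tree} / \code{ape::write.tree} so that
#' trees written by the pipeline round-trip through the reader.
#'
#' @param tree An \code{ape::phylo} object.
#' @param path File path.
#' @return \code{readNewick} returns a \code{phylo}; \code{writeNewick}
#'   returns the path invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  stopifnot(file.exists(path))
  ape::read.tree(path)
}

#' Labelled numeric matrix TSV I/O
#'
#' @param m Numeric matrix with row and column names.
#' @param path File path.
#' @return \code{readMatrixTSV} returns a matrix; \code{writeMatrixTSV}
#'   returns the path invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
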