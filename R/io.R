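#' Read a two-column chromosome sizes table
#'
#' @param path Tab-delimited file: chromosome name, length in bp.
#' @return Named integer vector.
#' @export
readChromSizes <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(parts)) {
        p <- parts[[i]]
        if (length(p) < 2 || is.na(suppressWarnings(as.integer(p[2]))))
            stop("line ", i, ": malformed chrom.sizes record")
    }
    setNames(vapply(parts, function(p) as.integer(p[2]), 1L),
             vapply(parts, `[[`, "", 1L))
}

#' @rdname readChromSizes
#' @param chromSizes Named vector of chromosome lengths.
#' @export
writeChromSizes <- function(chromSizes, path) {
    writeLines(paste(names(chromSizes), as.integer(chromSizes), sep = "\t"),
               path)
    invisible(path)
}

#' Read peak calls from BED or narrowPeak
#'
#' BED coordinates (0-based half-open) are converted to 1-based closed
#' GRanges. narrowPeak column 10 (summit offset from peak start; -1 = absent)
#' is stored as an absolute `summit` position.
#'
#' @param path Tab-delimited peak file.
#' @param format `"bed"` (>= 3 columns) or `"narrowPeak"` (10 columns).
#' @return GRanges sorted by (chromosome, start) with metadata `peak_id`,
#'   `score` and `summit` (NA when absent).
#' @export
readPeaks <- function(path, format = c("bed", "narrowPeak")) {
    format <- match.arg(format)
    lines <- readLines(path)
    keep <- nzchar(lines) & !startsWith(lines, "#") &
        !startsWith(lines, "track")
    lineNo <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    need <- if (format == "bed") 3L else 10L
    n <- length(parts)
    chrom <- character(n); s <- integer(n); e <- integer(n)
    name <- character(n); score <- numeric(n); summit <- integer(n)
    for (i in seq_len(n)) {
        p <- parts[[i]]
        if (length(p) < need)
            stop("line ", lineNo[i], ": expected >= ", need, " fields")
        si <- suppressWarnings(as.integer(p[2]))
        ei <- suppressWarnings(as.integer(p[3]))
        if (is.na(si) || is.na(ei))
            stop("line ", lineNo[i], ": non-integer coordinate")
        if (si >= ei)
            stop("line ", lineNo[i], ": start >= end")
        chrom[i] <- p[1]; s[i] <- si; e[i] <- ei
        name[i] <- if (length(p) >= 4) p[4] else paste0("peak_", i)
        score[i] <- if (length(p) >= 5)
            suppressWarnings(as.numeric(p[5])) else NA_real_
        summit[i] <- NA_integer_
        if (format == "narrowPeak") {
            off <- suppressWarnings(as.integer(p[10]))
            if (is.na(off))
                stop("line ", lineNo[i], ": non-integer summit offset")
            if (off >= ei - si)
                stop("line ", lineNo[i], ": summit offset beyond peak end")
            if (off >= 0) summit[i] <- si + off + 1L
        }
    }
    gr <- GRanges(chrom, IRanges(s + 1L, e))
    gr$peak_id <- name
    gr$score <- score
    gr$summit <- summit
    gr[order(as.character(seqnames(gr)), start(gr))]
}

#' Write peaks as BED6 or narrowPeak
#'
#' @param peaks GRanges with optional `peak_id`, `score`, `summit` metadata.
#' @param path Output path.
#' @param format `"bed"` (6 columns) or `"narrowPeak"` (10 columns).
#' @return The path, invisibly.
#' @export
writePeaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
    format <- match.arg(format)
    id <- if (!is.null(peaks$peak_id)) peaks$peak_id else
        paste0("peak_", seq_along(peaks))
    sc <- if (!is.null(peaks$score)) peaks$score else rep(0, length(peaks))
    sc[is.na(sc)] <- 0
    bedStart <- start(peaks) - 1L
    fields <- data.frame(as.character(seqnames(peaks)), bedStart, end(peaks),
                         id, format(sc, trim = TRUE), ".")
    if (format == "narrowPeak") {
        off <- rep(-1L, length(peaks))
        if (!is.null(peaks$summit)) {
            ok <- !is.na(peaks$summit)
            off[ok] <- peaks$summit[ok] - start(peaks)[ok]
        }
        fields <- cbind(fields, format(sc, trim = TRUE), "-1", "-1", off)
    }
    write.table(fields, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write Tn5 fragment intervals (BED3)
#'
#' @param path BED file of fragments.
#' @return GRanges of fragments.
#' @export
readFragments <- function(path) {
    p <- readPeaks(path, "bed")
    granges(p)
}

#' @rdname readFragments
#' @param fragments GRanges of fragments.
#' @export
writeFragments <- function(fragments, path) {
    write.table(data.frame(as.character(seqnames(fragments)),
                           start(fragments) - 1L, end(fragments)),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a genome annotation from GFF3 plus a chromosome sizes table
#'
#' Assembles one gene model per gene from gene/mRNA/exon/UTR records (the
#' longest transcript when several are present). GFF3 1-based inclusive
#' coordinates are kept as-is in GRanges.
#'
#' @param gffPath GFF3 file.
#' @param sizesPath Two-column chrom.sizes file.
#' @return A [GenomeAnnotation-class].
#' @export
readAnnotation <- function(gffPath, sizesPath) {
    cs <- readChromSizes(sizesPath)
    gff <- rtracklayer::import(gffPath, format = "gff3")
    if (length(gff)) {
        unknown <- !(as.character(seqnames(gff)) %in% names(cs))
        if (any(unknown))
            stop("GFF3 record on unknown chromosome: ",
                 paste(unique(as.character(seqnames(gff))[unknown]),
                       collapse = ", "))
        lim <- cs[as.character(seqnames(gff))]
        if (any(end(gff) > lim) || any(start(gff) < 1))
            stop("GFF3 coordinate exceeds chromosome size")
    }
    typ <- as.character(gff$type)
    genes <- gff[typ == "gene"]
    if (!length(genes))
        return(makeGenomeAnnotation(cs))
    genes$gene_id <- as.character(genes$ID)
    mrna <- gff[typ == "mRNA"]
    mrnaGene <- vapply(mrna$Parent, function(p) as.character(p)[1], "")
    ## longest transcript per gene
    keepTx <- unlist(lapply(split(seq_along(mrna), mrnaGene), function(idx) {
        idx[which.max(width(mrna)[idx])]
    }))
    txGene <- setNames(mrnaGene[keepTx], as.character(mrna$ID[keepTx]))
    childGene <- function(records) {
        if (!length(records)) return(GRanges())
        par <- vapply(records$Parent, function(p) as.character(p)[1], "")
        gid <- ifelse(par %in% names(txGene), txGene[par],
                      ifelse(par %in% genes$gene_id, par, NA_character_))
        keep <- !is.na(gid)
        out <- granges(records[keep])
        out$gene_id <- unname(gid[keep])
        out
    }
    ann <- makeGenomeAnnotation(
        cs,
        genes = {
            g <- granges(genes); g$gene_id <- genes$gene_id; g
        },
        exons = childGene(gff[typ == "exon"]),
        utr5 = childGene(gff[typ == "five_prime_UTR"]),
        utr3 = childGene(gff[typ == "three_prime_UTR"]))
    ann
}

#' Write a GenomeAnnotation as GFF3
#'
#' Emits gene, mRNA (one per gene, spanning the gene), exon and UTR records
#' with ID/Parent links, re-readable by [readAnnotation()].
#'
#' @param annotation A GenomeAnnotation.
#' @param path Output GFF3 path.
#' @return The path, invisibly.
#' @export
writeAnnotationGFF3 <- function(annotation, path) {
    g <- geneModels(annotation)
    rec <- function(gr, type, id, parent) {
        if (!length(gr)) return(GRanges())
        out <- granges(gr)
        out$source <- "acrdyn"
        out$type <- type
        out$ID <- id
        out$Parent <- parent
        out
    }
    txid <- paste0(g$gene_id, "_T001")
    names(txid) <- g$gene_id
    ex <- exonRanges(annotation)
    u5 <- utrRanges(annotation, "utr5")
    u3 <- utrRanges(annotation, "utr3")
    all <- c(
        rec(g, "gene", g$gene_id, NA_character_),
        rec(g, "mRNA", txid, g$gene_id),
        rec(ex, "exon", paste0(ex$gene_id, "_E",
                               seq_along(ex)), unname(txid[ex$gene_id])),
        rec(u5, "five_prime_UTR", paste0(u5$gene_id, "_U5_", seq_along(u5)),
            unname(txid[u5$gene_id])),
        rec(u3, "three_prime_UTR", paste0(u3$gene_id, "_U3_", seq_along(u3)),
            unname(txid[u3$gene_id])))
    if (length(all)) {
        all <- all[order(as.character(seqnames(all)), start(all),
                         match(all$type, c("gene", "mRNA", "exon",
                                           "five_prime_UTR",
                                           "three_prime_UTR")))]
    }
    seqlevels(all) <- names(chromSizes(annotation))
    seqlengths(all) <- unname(chromSizes(annotation))
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

#' Read / write a feature-by-sample numeric table (TSV)
#'
#' Header row of sample ids; first column holds feature ids.
#'
#' @param path TSV path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
readMatrixTSV <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                     check.names = FALSE)
    as.matrix(df)
}

#' @rdname readMatrixTSV
#' @param x Numeric matrix with rownames and colnames.
#' @export
writeMatrixTSV <- function(x, path) {
    df <- data.frame(feature = rownames(x), x, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Serialize / restore a TruthSet as JSON
#'
#' @param truth A TruthSet.
#' @param path JSON path.
#' @return The path (write) or a TruthSet (read).
#' @export
writeTruthSet <- function(truth, path) {
    jsonlite::write_json(list(
        peak_labels = peakLabels(truth),
        dpi_effects = dpiEffects(truth),
        peak_gene = peakGeneTruth(truth),
        gene_clusters = geneClusters(truth),
        discordant_genes = discordantGenes(truth),
        motif_placements = motifPlacements(truth)
    ), path, dataframe = "columns", digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeTruthSet
#' @export
readTruthSet <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    asDF <- function(y) as.data.frame(y, stringsAsFactors = FALSE)
    new("TruthSet",
        peakLabels = asDF(x$peak_labels),
        dpiEffects = asDF(x$dpi_effects),
        peakGene = asDF(x$peak_gene),
        geneClusters = asDF(x$gene_clusters),
        discordantGenes = as.character(unlist(x$discordant_genes)),
        motifPlacements = asDF(x$motif_placements))
}
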