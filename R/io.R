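## Readers and writers for the interchange formats: TSV / MatrixMarket
## expression matrices, SEG segment tables, minimal MAF mutation tables,
## BED gene models, regulon and cluster TSVs, and event-matrix TSVs.
## TSV is the canonical format; MTX serves large sparse matrices.

#' Read an expression matrix (TSV or MatrixMarket)
#'
#' TSV layout: header row of sample identifiers, first column gene
#' identifiers. MTX layout: a MatrixMarket file plus sidecar name files
#' (one identifier per line), by default `<path>.genes.txt` and
#' `<path>.samples.txt`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param units units tag for the result (default `"counts"`).
#' @param geneFile,sampleFile sidecar name files for MTX.
#' @return An [ExprMatrix-class].
#' @export
readExprMatrix <- function(path, format = c("tsv", "mtx"),
                           units = "counts", geneFile = NULL,
                           sampleFile = NULL) {
    format <- match.arg(format)
    if (format == "tsv") {
        df <- read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
        genes <- as.character(df[[1]])
        if (anyDuplicated(genes))
            stop("duplicate gene identifier(s) in ", path, ": ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", "))
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- genes
    } else {
        if (is.null(geneFile)) geneFile <- paste0(path, ".genes.txt")
        if (is.null(sampleFile)) sampleFile <- paste0(path, ".samples.txt")
        m <- as.matrix(Matrix::readMM(path))
        genes <- readLines(geneFile)
        samples <- readLines(sampleFile)
        if (nrow(m) != length(genes) || ncol(m) != length(samples))
            stop("MTX dimensions (", nrow(m), " x ", ncol(m),
                 ") do not match sidecar name files (", length(genes),
                 " x ", length(samples), ")")
        if (anyDuplicated(genes))
            stop("duplicate gene identifier(s) in ", geneFile, ": ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", "))
        dimnames(m) <- list(genes, samples)
    }
    ExprMatrix(m, units = units)
}

#' Write an expression matrix (TSV or MatrixMarket)
#'
#' @param x an [ExprMatrix-class] or matrix.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (MTX writes
#'   `<path>.genes.txt`/`<path>.samples.txt` sidecars).
#' @return `path`, invisibly.
#' @export
writeExprMatrix <- function(x, path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    m <- exprValues(x)
    if (format == "tsv") {
        df <- data.frame(gene = rownames(m), m, check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else {
        Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
        writeLines(rownames(m), paste0(path, ".genes.txt"))
        writeLines(colnames(m), paste0(path, ".samples.txt"))
    }
    invisible(path)
}

#' Read a SEG copy-number segment table
#'
#' Tab-separated with a header; columns `Sample`, `Chromosome`, `Start`,
#' `End`, `Segment_Mean` (a `Num_Probes` column is accepted and
#' ignored). SEG coordinates are 1-based inclusive and are kept as such
#' in the returned GRanges.
#'
#' @param path file path.
#' @return A [GenomicRanges::GRanges] with `sample_id` and `log2_ratio`
#'   metadata columns.
#' @export
readSeg <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("SEG file missing column(s): ", paste(miss, collapse = ", "))
    st <- suppressWarnings(as.numeric(df$Start))
    en <- suppressWarnings(as.numeric(df$End))
    bad <- which(!is.finite(st) | !is.finite(en) | en < st)
    if (length(bad))
        stop("malformed coordinates in ", path, " at line(s) ",
             paste(head(bad + 1L, 10), collapse = ", "))
    GRanges(as.character(df$Chromosome), IRanges(st, en),
            sample_id = as.character(df$Sample),
            log2_ratio = as.numeric(df$Segment_Mean))
}

#' Write CNV segments in SEG format
#'
#' @param segments [GenomicRanges::GRanges] with `sample_id` and
#'   `log2_ratio` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeg <- function(segments, path) {
    df <- data.frame(Sample = mcols(segments)$sample_id,
                     Chromosome = as.character(seqnames(segments)),
                     Start = start(segments), End = end(segments),
                     Num_Probes = width(segments) %/% 1000L + 1L,
                     Segment_Mean = mcols(segments)$log2_ratio)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a minimal MAF mutation table
#'
#' Requires columns `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`; extra columns are kept.
#'
#' @param path file path.
#' @return A data frame.
#' @export
readMaf <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
              "Variant_Classification")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("MAF file missing column(s): ", paste(miss, collapse = ", "))
    df
}

#' Write a minimal MAF mutation table
#'
#' @param maf data frame with the three minimal MAF columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaf <- function(maf, path) {
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
              "Variant_Classification")
    miss <- setdiff(need, colnames(maf))
    if (length(miss))
        stop("MAF table missing column(s): ", paste(miss, collapse = ", "))
    write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene models from a BED file
#'
#' BED uses 0-based half-open coordinates; they are converted to the
#' 1-based closed convention of GRanges on read.
#'
#' @param path file path (no header; columns chrom, start, end, name).
#' @return A [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
readBed <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4)
        stop("BED file needs at least 4 columns (chrom, start, end, name)")
    st <- suppressWarnings(as.numeric(df[[2]]))
    en <- suppressWarnings(as.numeric(df[[3]]))
    bad <- which(!is.finite(st) | !is.finite(en) | en <= st)
    if (length(bad))
        stop("malformed coordinates in ", path, " at line(s) ",
             paste(head(bad, 10), collapse = ", "))
    GRanges(as.character(df[[1]]), IRanges(st + 1L, en),
            gene_id = as.character(df[[4]]))
}

#' Write gene models to a BED file
#'
#' @param genes [GenomicRanges::GRanges] with a `gene_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(genes, path) {
    df <- data.frame(as.character(seqnames(genes)), start(genes) - 1L,
                     end(genes), mcols(genes)$gene_id)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read regulons from a three-column TSV
#'
#' Columns `tf`, `target`, `mode` (+1/-1) with a header. TFs with fewer
#' than 10 targets are dropped with a warning.
#'
#' @param path file path.
#' @return A named list of [Regulon-class] objects.
#' @export
readRegulons <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("tf", "target", "mode")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("regulon file missing column(s): ",
             paste(miss, collapse = ", "))
    out <- list()
    dropped <- character(0)
    for (tf in unique(df$tf)) {
        sub <- df[df$tf == tf, , drop = FALSE]
        if (length(setdiff(sub$target, tf)) < 10L) {
            dropped <- c(dropped, tf)
            next
        }
        out[[tf]] <- Regulon(tf, sub$target, sub$mode)
    }
    if (length(dropped))
        warning("dropped TF(s) with < 10 targets: ",
                paste(dropped, collapse = ", "))
    if (!length(out))
        stop("no usable regulons in ", path)
    out
}

#' Write regulons to a three-column TSV
#'
#' @param regulons list of [Regulon-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegulons <- function(regulons, path) {
    df <- do.call(rbind, lapply(regulons, function(r)
        data.frame(tf = regulonTf(r), target = regulonTargets(r),
                   mode = unname(regulonModes(r)))))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene clusters from a two-column TSV
#'
#' Columns `cluster_id`, `gene` with a header.
#'
#' @param path file path.
#' @return A named list of character vectors.
#' @export
readClusters <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("cluster_id", "gene")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("cluster file missing column(s): ",
             paste(miss, collapse = ", "))
    split(as.character(df$gene), df$cluster_id)
}

#' Write gene clusters to a two-column TSV
#'
#' @param clusters named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClusters <- function(clusters, path) {
    df <- data.frame(cluster_id = rep(names(clusters),
                                      lengths(clusters)),
                     gene = unlist(clusters, use.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write an event matrix as TSV
#'
#' Event identifiers are `"<gene>:<class>"` in the first column; sample
#' identifiers form the header.
#'
#' @param path file path.
#' @return [readEventMatrix()]: an [EventMatrix-class].
#' @export
readEventMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    parts <- regmatches(ids, regexpr(":[^:]*$", ids))
    geneIds <- sub(":[^:]*$", "", ids)
    classes <- sub("^:", "", parts)
    v <- as.matrix(df[, -1, drop = FALSE])
    EventMatrix(v, geneIds, classes, colnames(v))
}

#' @rdname readEventMatrix
#' @param x an [EventMatrix-class].
#' @export
writeEventMatrix <- function(x, path) {
    df <- data.frame(event = rownames(x), eventValues(x),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a simulated cohort's artifacts to a directory
#'
#' Writes counts (TSV), truth events (TSV), CNV segments (SEG),
#' mutations (minimal MAF), regulons (TSV), clusters (TSV) and gene
#' models (BED), using the standard readers' conventions.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeExprMatrix(cohortCounts(cohort), file.path(dir, "counts.tsv"))
    writeEventMatrix(truthEvents(cohort), file.path(dir, "events.tsv"))
    if (length(cohortSegments(cohort)))
        writeSeg(cohortSegments(cohort), file.path(dir, "segments.seg"))
    tr <- truthEvents(cohort)
    mutRows <- which(eventClasses(tr) == "mutation")
    if (length(mutRows)) {
        v <- eventValues(tr)[mutRows, , drop = FALSE]
        g <- rowData(tr)$gene_id[mutRows]
        idx <- which(v == 1, arr.ind = TRUE)
        maf <- data.frame(Hugo_Symbol = g[idx[, 1]],
                          Tumor_Sample_Barcode = colnames(v)[idx[, 2]],
                          Variant_Classification = "Missense_Mutation")
        writeMaf(maf, file.path(dir, "mutations.maf"))
    }
    writeRegulons(cohortRegulons(cohort), file.path(dir, "regulons.tsv"))
    writeClusters(cohortClusters(cohort), file.path(dir, "clusters.tsv"))
    writeBed(geneModels(cohort), file.path(dir, "genes.bed"))
    invisible(dir)
}

#' Write a perturbation sweep to disk with a manifest
#'
#' Writes each perturbed matrix of a [perturbationSweep()] as TSV and a
#' tab-separated manifest recording, per entry: level, repetition, seed,
#' output path, realized total reads and dropout (zero) fraction.
#'
#' @param sweep result of [perturbationSweep()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writePerturbationSweep <- function(sweep, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rows <- lapply(seq_along(sweep), function(i) {
        e <- sweep[[i]]
        m <- exprValues(e$matrix)
        path <- file.path(dir, sprintf("perturbed_L%g_r%03d.tsv",
                                       e$level, e$rep))
        writeExprMatrix(e$matrix, path)
        data.frame(level = e$level, rep = e$rep, seed = e$seed,
                   path = path, total_reads = sum(m),
                   dropout_fraction = mean(m == 0))
    })
    manifest <- file.path(dir, "manifest.tsv")
    write.table(do.call(rbind, rows), manifest, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(manifest)
}

#' Write per-event model results as TSV
#'
#' One row per completed repetition: event, algorithm, rep, AUROC, and
#' any constant metadata columns supplied (e.g. perturbation level).
#'
#' @param dist an `AurocDistribution` from [repeatedEvaluation()] or
#'   [bootstrapEvaluation()], or a list of them.
#' @param path output path.
#' @param metadata named list of constant columns added to every row.
#' @return `path`, invisibly.
#' @export
writeModelResults <- function(dist, path, metadata = list()) {
    if (inherits(dist, "AurocDistribution")) dist <- list(dist)
    rows <- do.call(rbind, lapply(dist, function(d) {
        ok <- which(!is.na(d$aurocs))
        df <- data.frame(event_id = if (is.null(d$eventId)) NA else
                                    d$eventId,
                         algorithm = d$algorithm, rep = ok,
                         auroc = d$aurocs[ok])
        for (nm in names(metadata)) df[[nm]] <- metadata[[nm]]
        df
    }))
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a model specification from a YAML file
#'
#' Accepts the [modelSpec()] fields (`algorithm`, `cvFolds`,
#' `trainFrac`, `seed`, `hyperparameters`); missing fields take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `ModelSpec`.
#' @export
readModelSpec <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read model specs")
    cfg <- yaml::read_yaml(path)
    known <- c("algorithm", "cvFolds", "trainFrac", "seed",
               "hyperparameters")
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop("unknown model spec field(s): ", paste(bad, collapse = ", "))
    do.call(modelSpec, cfg)
}
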