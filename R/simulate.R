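#' @include AllClasses.R reference.R
NULL

# utf8 code of N, used throughout for masking
.N_INT <- utf8ToInt("N")

# utf8 code -> 1:5 for A,C,G,T,N
.CODE <- local({
    v <- integer(128L)
    v[utf8ToInt("ACGTN")] <- 1:5
    v
})

# row = .CODE of current base, columns = the 3 substitution alternatives
.ALT3 <- local({
    alt <- function(b) utf8ToInt(paste(setdiff(.BASES, b), collapse = ""))
    rbind(alt("A"), alt("C"), alt("G"), alt("T"), utf8ToInt("ACG"))
})

# deterministic per-read child seed: changing nReads never perturbs the
# streams of earlier reads
.childSeed <- function(seed, i) {
    s <- (as.numeric(seed) %% 2147483647) * 1048576 + as.numeric(i)
    s <- s %% 2147483647
    if (s == 0) s <- 1
    as.integer(s)
}

.checkWeights <- function(w) {
    if (!setequal(names(w), .CTX_KEYS))
        stop("context weights must be named exactly ",
             paste(.CTX_KEYS, collapse = ", "))
    if (any(is.na(w)) || any(w < 0 | w > 1))
        stop("context weights must be probabilities in [0,1]")
    w[.CTX_KEYS]
}

#' Generate a synthetic circular reference sequence
#'
#' Draws an i.i.d. DNA sequence with mitochondrial-like base composition
#' (the rCRS heavy strand is A/C rich and G poor). Intended as a stand-in
#' coordinate system for simulations and tests; it is synthetic, not the
#' rCRS.
#'
#' @param length Sequence length in nt (default the rCRS length, 16,569).
#' @param seed Integer seed.
#' @param composition Named base probabilities for A, C, G, T.
#' @param name Record identifier.
#' @param circular Topology of the generated reference.
#' @return A [MitoReference].
#' @export
simulateReference <- function(length = 16569L, seed = 1L,
                              composition = c(A = 0.309, C = 0.313,
                                              G = 0.131, T = 0.247),
                              name = "synthetic_mito", circular = TRUE) {
    stopifnot(length >= 1L, setequal(names(composition), .BASES))
    set.seed(seed)
    seq <- paste(sample(.BASES, length, replace = TRUE,
                        prob = composition[.BASES]), collapse = "")
    mitoReference(seq, circular = circular, name = name)
}

#' Simulation settings constructor
#'
#' Defaults describe the study conditions the package models: 250 nt amplicon
#' reads, complement-strand deamination (seen as G->A on the reference
#' strand) with the APOBEC3 context preference TpC > CpC >> ApC/GpC, a 1e-4
#' uniform per-base error rate, and 1% of reads exposed to deamination.
#'
#' @param region [GenomeRegion] reads are drawn from.
#' @param nReads,readLength Library size and read length.
#' @param pHyper Fraction of reads exposed to deamination.
#' @param strand Deaminated strand, `"complement"` or `"reference"`.
#' @param contextWeights Named per-site deamination probabilities
#'   (`TpC`, `CpC`, `ApC`, `GpC`).
#' @param errorRate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return A [SimulationConfig].
#' @export
simulationConfig <- function(region, nReads = 10000L, readLength = 250L,
                             pHyper = 0.01,
                             strand = c("complement", "reference"),
                             contextWeights = c(TpC = 0.7, CpC = 0.25,
                                                ApC = 0.025, GpC = 0.025),
                             errorRate = 1e-4, seed = 1L) {
    strand <- match.arg(strand)
    new("SimulationConfig", region = region, nReads = as.integer(nReads),
        readLength = as.integer(readLength), pHyper = pHyper, strand = strand,
        contextWeights = .checkWeights(contextWeights), errorRate = errorRate,
        seed = as.integer(seed))
}

# per-column deamination probability over a region for a given strand:
# list(p = per-column probability, positions = reference coordinates,
#      altInt = utf8 code of the as-written alternate base,
#      nDroppedContext = eligible sites with unresolvable context)
.siteProfile <- function(ref, region, strand, weights) {
    weights <- .checkWeights(weights)
    posv <- .regionPositions(ref, region)
    bases <- substring(ref@seq, posv, posv)
    target <- if (strand == "reference") "C" else "G"
    elig <- which(bases == target)
    p <- numeric(length(posv))
    dropped <- 0L
    if (length(elig)) {
        ctx <- dinucleotideContext(ref, posv[elig], strand)
        dropped <- sum(is.na(ctx))
        w <- ifelse(is.na(ctx), 0, weights[ctx])
        p[elig] <- w
    }
    list(p = p, positions = posv,
         altInt = utf8ToInt(if (strand == "reference") "T" else "A"),
         nDroppedContext = dropped)
}

#' Apply strand-specific cytidine deamination to one read
#'
#' Each eligible site (C for `strand = "reference"`, G -- a complement-strand
#' C -- for `strand = "complement"`) mutates independently with the
#' probability assigned to its 5'-dinucleotide context. Only C->T
#' (respectively G->A) changes, as written on the reference strand, are ever
#' introduced.
#'
#' @param seq Read sequence; must match the reference over its interval.
#' @param offset 1-based reference coordinate of the first base (may wrap on
#'   a circular reference).
#' @param ref A [MitoReference].
#' @param strand Deaminated strand.
#' @param contextWeights Named per-site deamination probabilities.
#' @return `list(seq = mutated sequence, positions = deaminated 1-based
#'   reference positions)`.
#' @export
applyHypermutation <- function(seq, offset, ref,
                               strand = c("complement", "reference"),
                               contextWeights) {
    strand <- match.arg(strand)
    weights <- .checkWeights(contextWeights)
    L <- nchar(seq)
    len <- length(ref)
    if (ref@circular) {
        idx <- ((as.integer(offset) - 1L + 0:(L - 1L)) %% len) + 1L
    } else {
        idx <- as.integer(offset) + 0:(L - 1L)
        if (any(idx < 1L | idx > len))
            stop("read interval off the end of a linear reference")
    }
    refwin <- substring(ref@seq, idx, idx)
    u <- utf8ToInt(seq)
    if (any(utf8ToInt(paste(refwin, collapse = "")) != u))
        stop("read does not match the reference over its interval")
    target <- if (strand == "reference") "C" else "G"
    elig <- which(refwin == target)
    p <- numeric(L)
    if (length(elig)) {
        ctx <- dinucleotideContext(ref, idx[elig], strand)
        p[elig] <- ifelse(is.na(ctx), 0, weights[ctx])
    }
    hit <- which(stats::runif(L) < p)
    if (length(hit))
        u[hit] <- utf8ToInt(if (strand == "reference") "T" else "A")
    list(seq = intToUtf8(u), positions = idx[hit])
}

#' Apply uniform sequencing/PCR substitution errors
#'
#' Each base is independently replaced with probability `errorRate` by one of
#' the three other bases, chosen uniformly.
#'
#' @param seq Read sequence.
#' @param errorRate Per-base substitution probability in `[0,1]`.
#' @return The sequence after errors.
#' @export
applySequencingErrors <- function(seq, errorRate) {
    stopifnot(errorRate >= 0, errorRate <= 1)
    n <- nchar(seq)
    if (errorRate == 0 || n == 0L) return(seq)
    k <- stats::rbinom(1L, n, errorRate)
    if (k == 0L) return(seq)
    pos <- sample.int(n, k)
    u <- utf8ToInt(seq)
    pick <- sample.int(3L, k, replace = TRUE)
    u[pos] <- .ALT3[cbind(.CODE[u[pos]], pick)]
    intToUtf8(u)
}

#' Simulate an amplicon read library with truth labels
#'
#' Read start positions are uniform over the region (reads never extend past
#' the region's end); deamination is applied before sequencing error.
#' Randomness is drawn from one deterministic child stream per read index, so
#' enlarging `nReads` reproduces the earlier reads exactly.
#'
#' @param config A [SimulationConfig].
#' @param ref A [MitoReference].
#' @return A [ReadLibrary] with truth labels.
#' @export
simulateLibrary <- function(config, ref) {
    region <- config@region
    Lr <- regionLength(ref, region)
    L <- config@readLength
    if (L > Lr)
        stop(sprintf("region length %d shorter than read length %d", Lr, L))
    prof <- .siteProfile(ref, region, config@strand, config@contextWeights)
    regInt <- utf8ToInt(extractRegion(ref, region))
    maxStart <- Lr - L + 1L
    n <- config@nReads
    eps <- config@errorRate
    pH <- config@pHyper

    seqs <- character(n)
    offs <- integer(n)
    dstr <- character(n)
    win <- 0:(L - 1L)
    for (i in seq_len(n)) {
        set.seed(.childSeed(config@seed, i))
        s <- if (maxStart == 1L) 1L else sample.int(maxStart, 1L)
        u <- regInt[s + win]
        dp <- integer(0L)
        if (pH > 0 && stats::runif(1L) < pH) {
            hit <- which(stats::runif(L) < prof$p[s + win])
            if (length(hit)) {
                u[hit] <- prof$altInt
                dp <- prof$positions[s - 1L + hit]
            }
        }
        if (eps > 0) {
            k <- stats::rbinom(1L, L, eps)
            if (k > 0L) {
                pos <- sample.int(L, k)
                pick <- sample.int(3L, k, replace = TRUE)
                u[pos] <- .ALT3[cbind(.CODE[u[pos]], pick)]
            }
        }
        seqs[i] <- intToUtf8(u)
        offs[i] <- prof$positions[s]
        dstr[i] <- paste(dp, collapse = ",")
    }
    ids <- sprintf("read%06d", seq_len(n))
    truth <- data.frame(read_id = ids, is_hypermutated = nzchar(dstr),
                        deaminated_positions = dstr,
                        stringsAsFactors = FALSE)
    new("ReadLibrary", ids = ids, reads = seqs, offsets = offs, truth = truth,
        region = region, config = config)
}

#' Write a simulated library to FASTA/FASTQ (plus truth TSV)
#'
#' Each read's true reference offset is recorded in its header as
#' `offset=<pos>`. FASTQ output carries a constant quality.
#'
#' @param lib A [ReadLibrary].
#' @param path Output reads file.
#' @param truthPath Optional truth-label TSV
#'   (`read_id`, `is_hypermutated`, `deaminated_positions`).
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return `path`, invisibly.
#' @export
writeLibrary <- function(lib, path, truthPath = NULL,
                         format = c("fasta", "fastq")) {
    format <- match.arg(format)
    x <- Biostrings::DNAStringSet(lib@reads)
    names(x) <- sprintf("%s offset=%d", lib@ids, lib@offsets)
    if (format == "fasta") {
        Biostrings::writeXStringSet(x, path)
    } else {
        q <- Biostrings::PhredQuality(
            vapply(nchar(lib@reads), function(n)
                   paste(rep("I", n), collapse = ""), ""))
        Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    }
    if (!is.null(truthPath))
        utils::write.table(lib@truth, truthPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(path)
}

#' Read an amplicon library from FASTA/FASTQ
#'
#' Parses `offset=<pos>` from headers when present (declared mapping
#' offsets, as written by [writeLibrary()]).
#'
#' @param path FASTA or FASTQ file.
#' @param format Input format; `"fasta"` default.
#' @return `list(ids, reads, offsets)`; `offsets` is NULL when no header
#'   declares one.
#' @export
readLibraryFile <- function(path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    set <- Biostrings::readBStringSet(path, format = format)
    if (length(set) == 0L)
        stop("no reads in ", path)
    hdr <- names(set)
    ids <- sub("\\s.*$", "", hdr)
    m <- regmatches(hdr, regexpr("offset=\\d+", hdr))
    offsets <- NULL
    if (length(m) == length(hdr) && all(nzchar(m)))
        offsets <- as.integer(sub("offset=", "", m))
    list(ids = ids, reads = unname(toupper(as.character(set))),
         offsets = offsets)
}

#' Fit the 3D-PCR melting-temperature model
#'
#' Ordinary least squares of the lowest amplification temperature on the
#' number of C->T (or G->A) mutations, `Tm(m) = tm0 - delta * m`.
#'
#' @param mutations Mutation counts (>= 2 distinct values).
#' @param temperatures Lowest amplification temperatures (degrees C).
#' @return A [TmModel].
#' @examples
#' fitTmModel(c(0, 4, 17), c(84.9, 84.1, 82.6))
#' @export
fitTmModel <- function(mutations, temperatures) {
    if (length(mutations) != length(temperatures))
        stop("'mutations' and 'temperatures' must have equal length")
    if (length(unique(mutations)) < 2L)
        stop("need at least 2 distinct mutation counts to fit a line")
    fit <- stats::lm(temperatures ~ mutations)
    slope <- unname(stats::coef(fit)[2L])
    if (!is.finite(slope) || slope >= 0)
        stop("amplification temperature must decrease with mutation load")
    new("TmModel", tm0 = unname(stats::coef(fit)[1L]), delta = -slope)
}

#' Predicted lowest amplification temperature at a mutation load
#'
#' @param model A [TmModel].
#' @param load Mutation count(s).
#' @return `tm0 - delta * load`, degrees C.
#' @export
predictTm <- function(model, load) model@tm0 - model@delta * load

#' In-silico 3D-PCR denaturation selection
#'
#' Differential-denaturation PCR run at denaturation temperature `td`
#' amplifies a template only if its predicted melting temperature does not
#' exceed `td`; selection is deterministic in the mutation load.
#'
#' @param loads Per-read C->T/G->A mutation counts.
#' @param model A [TmModel].
#' @param td Denaturation temperature (degrees C, > 0).
#' @return Logical vector: TRUE where the read survives.
#' @export
simulate3dpcr <- function(loads, model, td) {
    stopifnot(td > 0)
    predictTm(model, loads) <= td
}
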