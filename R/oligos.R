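## Sequence-level representation of the assay's oligo designs: a DNAStringSet
## subclass carrying 5'/3' modification tags, with in-silico ligation,
## primer/probe siting and amplicon extraction.

.MOD5_TAGS <- c("none", "biotin", "phosphate", "ROX", "FAM")
.MOD3_TAGS <- c("none", "biotin", "MGB")

#' Oligonucleotide collection with terminal modification tags
#'
#' `OligoSet` extends [Biostrings::DNAStringSet] with per-record `mod5` and
#' `mod3` metadata columns recording chemical tags at the 5' and 3' termini
#' (biotin, 5'-phosphate, ROX/FAM fluorophores, MGB quencher). Modifications
#' are metadata only and never enter the sequence alphabet, which is
#' restricted to unambiguous upper-case A/C/G/T. Names must be unique and
#' non-empty.
#'
#' @slot .Data,ranges,elementMetadata,... inherited from `DNAStringSet`.
#' @seealso [oligoSet()], [readOligos()], [assayOligos()]
#' @export
setClass("OligoSet", contains = "DNAStringSet")

setValidity("OligoSet", function(object) {
  msgs <- character()
  n <- length(object)
  nm <- names(object)
  if (n > 0 && (is.null(nm) || any(!nzchar(nm)) || anyNA(nm)))
    msgs <- c(msgs, "all records must be named")
  if (!is.null(nm) && anyDuplicated(nm))
    msgs <- c(msgs, paste0("duplicate record names: ",
                           paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (n > 0) {
    af <- Biostrings::alphabetFrequency(object, baseOnly = TRUE)
    if (any(af[, "other"] > 0))
      msgs <- c(msgs, "sequences must contain only A/C/G/T")
    if (any(Biostrings::width(object) == 0))
      msgs <- c(msgs, "sequences must be non-empty")
  }
  mc <- S4Vectors::mcols(object)
  if (is.null(mc) || !all(c("mod5", "mod3") %in% colnames(mc))) {
    msgs <- c(msgs, "metadata columns 'mod5' and 'mod3' are required")
  } else {
    if (!all(mc$mod5 %in% .MOD5_TAGS))
      msgs <- c(msgs, paste0("mod5 tags must be one of: ",
                             paste(.MOD5_TAGS, collapse = ", ")))
    if (!all(mc$mod3 %in% .MOD3_TAGS))
      msgs <- c(msgs, paste0("mod3 tags must be one of: ",
                             paste(.MOD3_TAGS, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OligoSet
#'
#' @param sequences named character vector (or `DNAStringSet`) of 5'->3'
#'   sequences over A/C/G/T.
#' @param mod5,mod3 terminal modification tags, recycled to the collection
#'   length; `mod5` from `none, biotin, phosphate, ROX, FAM`; `mod3` from
#'   `none, biotin, MGB`.
#' @return an [OligoSet].
#' @examples
#' oligoSet(c(fwd = "ACGTACGTACGT"), mod5 = "biotin")
#' @export
oligoSet <- function(sequences, mod5 = "none", mod3 = "none") {
  if (is.character(sequences)) {
    .checkDnaCharacters(sequences)
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  n <- length(sequences)
  S4Vectors::mcols(sequences) <- S4Vectors::DataFrame(
    mod5 = rep_len(as.character(mod5), n),
    mod3 = rep_len(as.character(mod3), n))
  new("OligoSet", sequences)
}

#' Fail on non-ACGT characters, naming the first offending position.
#' @noRd
.checkDnaCharacters <- function(seqs) {
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGT]", seqs[[i]])
    if (bad > 0)
      stop("invalid character '", substr(seqs[[i]], bad, bad),
           "' at position ", bad,
           if (!is.null(names(seqs))) paste0(" of '", names(seqs)[i], "'"),
           " (sequences must be upper-case A/C/G/T)", call. = FALSE)
  }
  invisible(seqs)
}

#' @describeIn oligoSet 5' modification tags of the records.
#' @param x an `OligoSet`.
#' @export
oligoMod5 <- function(x) setNames(S4Vectors::mcols(x)$mod5, names(x))

#' @describeIn oligoSet 3' modification tags of the records.
#' @export
oligoMod3 <- function(x) setNames(S4Vectors::mcols(x)$mod3, names(x))

#' @noRd
.getOligo <- function(x, name) {
  if (!name %in% names(x))
    stop("no oligo named '", name, "' in the collection", call. = FALSE)
  x[name]
}

setMethod("show", "OligoSet", function(object) {
  cat("OligoSet with", length(object), "records\n")
  if (length(object)) {
    df <- data.frame(width = Biostrings::width(object),
                     mod5 = oligoMod5(object),
                     mod3 = oligoMod3(object),
                     row.names = names(object))
    print(df)
  }
})

#' Reverse complement of a DNA sequence
#'
#' Thin, validating wrapper around [Biostrings::reverseComplement()] for plain
#' character input. Watson-Crick complement, reversed; an involution.
#'
#' @param seq single 5'->3' DNA string over A/C/G/T.
#' @return the reverse complement as a character string.
#' @examples
#' revComp("ACGT")                    # palindrome
#' revComp("AGTGAGTCTTGCTGAAGCGG")    # probe -> its template site
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .checkDnaCharacters(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' In-silico ligation of two oligos
#'
#' Joins `upstream` 3' end to `downstream` 5' end, the product of a
#' nick-sealing ligase acting on two strands held end-to-end by a bridging
#' connector. Ligation chemistry requires a 5'-phosphate on the downstream
#' strand, so the call refuses otherwise. The connector's bridging geometry is
#' not sequence-verified (its printed complementarity to the junction is only
#' partial); it is carried as metadata of the event.
#'
#' @param oligos an [OligoSet].
#' @param upstream,downstream record names of the strands to join.
#' @param connector optional record name of the bridging oligo.
#' @return an [OligoSet] with the single ligation product, named
#'   `"<upstream>+<downstream>"`; `mod5` from upstream, `mod3` from downstream.
#' @examples
#' tbl <- assayOligos()
#' lig <- ligateOligos(tbl, "Proximity_C1", "Proximity_C2", "Proximity_cnct")
#' Biostrings::width(lig)  # 111, the full-length template
#' @export
ligateOligos <- function(oligos, upstream, downstream, connector = NULL) {
  stopifnot(is(oligos, "OligoSet"))
  up <- .getOligo(oligos, upstream)
  down <- .getOligo(oligos, downstream)
  if (!is.null(connector)) .getOligo(oligos, connector)
  if (oligoMod5(down) != "phosphate")
    stop("downstream oligo '", downstream, "' lacks a 5'-phosphate (mod5 = '",
         oligoMod5(down), "'); ligase cannot seal the nick", call. = FALSE)
  seq <- paste0(as.character(up[[1]]), as.character(down[[1]]))
  oligoSet(setNames(seq, paste0(upstream, "+", downstream)),
           mod5 = unname(oligoMod5(up)), mod3 = unname(oligoMod3(down)))
}

#' Primer-pair footprint on a template
#'
#' Coordinates of an in-silico PCR product: 0-based, half-open, spanning both
#' primer footprints.
#'
#' @slot template_name template record name.
#' @slot start 0-based inclusive index of the forward primer's 5' end.
#' @slot end 0-based exclusive index just past the reverse primer binding site.
#' @slot length amplicon length in nucleotides (`end - start`).
#' @seealso [findAmplicon()]
#' @export
setClass("AmpliconHit",
         representation(template_name = "character", start = "integer",
                        end = "integer", length = "integer"))

setValidity("AmpliconHit", function(object) {
  if (object@start < 0 || object@start >= object@end)
    return("need 0 <= start < end")
  if (object@length != object@end - object@start)
    return("length must equal end - start")
  TRUE
})

setMethod("show", "AmpliconHit", function(object) {
  cat(sprintf("AmpliconHit on '%s': [%d, %d), %d nt\n", object@template_name,
              object@start, object@end, object@length))
})

#' @describeIn findAmplicon accessor for the amplicon length (nt).
#' @param hit an `AmpliconHit`.
#' @export
ampliconLength <- function(hit) hit@length

#' Locate a primer pair on a template (in-silico PCR)
#'
#' Finds the forward primer as an exact substring of the template and the
#' reverse complement of the reverse primer as an exact substring downstream
#' of it. Exact matching only: no mismatch tolerance and no thermodynamics,
#' so a single printed-sequence discrepancy (as with the EXO reverse primer
#' against the 69-mer) surfaces as "no amplicon" rather than being silently
#' repaired.
#'
#' @param oligos an [OligoSet].
#' @param template,fwd,rev record names of the template and primer pair;
#'   primers must be at least 15 nt.
#' @return an [AmpliconHit] (first forward site, first compatible reverse
#'   site).
#' @examples
#' tbl <- assayOligos()
#' findAmplicon(tbl, "C1C2", "Proximity_F", "Proximity_R")  # 87 nt
#' @export
findAmplicon <- function(oligos, template, fwd, rev) {
  stopifnot(is(oligos, "OligoSet"))
  tmpl <- .getOligo(oligos, template)[[1]]
  fseq <- .getOligo(oligos, fwd)[[1]]
  rseq <- .getOligo(oligos, rev)[[1]]
  if (length(fseq) < 15L || length(rseq) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  fhits <- Biostrings::matchPattern(fseq, tmpl)
  if (length(fhits) == 0L)
    stop("no amplicon: forward primer '", fwd,
         "' not found on template '", template, "'", call. = FALSE)
  rhits <- Biostrings::matchPattern(Biostrings::reverseComplement(rseq), tmpl)
  if (length(rhits) == 0L)
    stop("no amplicon: reverse-complement of reverse primer '", rev,
         "' not found on template '", template, "'", call. = FALSE)
  fstart <- BiocGenerics::start(fhits)[1L] - 1L          # to 0-based
  ok <- BiocGenerics::start(rhits) - 1L >= fstart
  if (!any(ok))
    stop("no amplicon: reverse primer site lies upstream of the forward ",
         "primer site on template '", template, "'", call. = FALSE)
  rend <- BiocGenerics::end(rhits)[which(ok)[1L]]        # 1-based incl = 0-based excl
  new("AmpliconHit", template_name = template, start = fstart,
      end = as.integer(rend), length = as.integer(rend - fstart))
}

#' Read / write oligo collections as FASTA
#'
#' Modifications are encoded in the description line as `mod5=<tag>` /
#' `mod3=<tag>` tokens after the record name; absent tokens default to
#' `none`. A write-then-read round trip is the identity.
#'
#' @param path FASTA file path.
#' @return `readOligos()`: an [OligoSet] (empty file gives an empty set);
#'   `writeOligos()`: `path`, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeOligos(oligoSet(c(a = "ACGT"), mod5 = "biotin"), tf)
#' readOligos(tf)
#' @export
readOligos <- function(path) {
  if (file.size(path) == 0)
    return(oligoSet(Biostrings::DNAStringSet()))
  dss <- Biostrings::readDNAStringSet(path)
  hdr <- names(dss)
  toks <- strsplit(hdr, "[[:space:]]+")
  nm <- vapply(toks, `[`, "", 1L)
  pick <- function(tok, key) {
    hit <- grep(paste0("^", key, "="), tok, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else "none"
  }
  mod5 <- vapply(toks, pick, "", key = "mod5")
  mod3 <- vapply(toks, pick, "", key = "mod3")
  if (anyDuplicated(nm))
    stop("duplicate oligo names in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(dss) <- nm
  .checkDnaCharacters(setNames(as.character(dss), nm))
  oligoSet(dss, mod5 = mod5, mod3 = mod3)
}

#' @rdname readOligos
#' @param oligos an [OligoSet] to serialize.
#' @export
writeOligos <- function(oligos, path) {
  stopifnot(is(oligos, "OligoSet"))
  out <- Biostrings::DNAStringSet(as.character(oligos))
  names(out) <- sprintf("%s mod5=%s mod3=%s", names(oligos),
                        oligoMod5(oligos), oligoMod3(oligos))
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' The packaged assay oligo designs
#'
#' Loads the packaged FASTA of the assay's oligonucleotides: the biotinylated
#' 69-mer reference amplicon with its primer pair and ROX probe, the
#' proximity-ligation strands C1/C2 (plain and biotinylated), the bridging
#' connector, the proximity primer pair, the TaqMan probe, and the synthetic
#' full-length ligation product C1C2. Record names use underscores where the
#' published table uses spaces.
#'
#' @return an [OligoSet] with 13 records.
#' @examples
#' assayOligos()
#' @export
assayOligos <- function() {
  readOligos(system.file("extdata", "table1.fasta", package = "evImmunoPCR",
                         mustWork = TRUE))
}
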