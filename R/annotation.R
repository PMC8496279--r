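# Extraction of short-intron (SI) sites from annotation, intersection of
# homologous sites through whole-genome-alignment columns, and the site
# filters.  All user-facing coordinates are 0-based half-open; GFF3
# (1-based inclusive) and BED (0-based half-open) are converted at the
# boundary.

read_gff3_features <- function(gff) {
  if (is.character(gff)) {
    lines <- readr::read_lines(gff)
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    parts <- strsplit(lines[body], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 9L)
    if (length(bad) > 0) {
      abort(sprintf("Malformed GFF3 record at line %d (expected 9 fields).",
                    body[bad[1]]))
    }
    f <- as_tibble(do.call(rbind, parts), .name_repair = "minimal")
    names(f) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes")
    f$start <- suppressWarnings(as.integer(f$start))
    f$end <- suppressWarnings(as.integer(f$end))
    if (anyNA(f$start) || anyNA(f$end)) {
      abort(sprintf("Non-numeric coordinates at GFF3 line %d.",
                    body[which(is.na(f$start) | is.na(f$end))[1]]))
    }
    f
  } else {
    as_tibble(gff)
  }
}

gff_attr <- function(attributes, key) {
  m <- stringr::str_match(attributes, paste0("(?:^|;)", key, "=([^;]+)"))
  m[, 2]
}

# Introns per transcript: explicit intron features if present, otherwise
# the gaps between a transcript's exons.
derive_introns <- function(features) {
  if (any(features$type == "intron")) {
    ints <- features |> filter(.data$type == "intron")
    return(tibble(
      seqid = ints$seqid, start = ints$start, end = ints$end,
      strand = ints$strand
    ))
  }
  exons <- features |>
    filter(.data$type == "exon") |>
    mutate(parent = gff_attr(.data$attributes, "Parent"))
  exons |>
    group_by(.data$seqid, .data$strand, .data$parent) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      istart = list(utils::head(.data$end + 1L, -1L)),
      iend = list(utils::tail(.data$start - 1L, -1L)),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("istart", "iend")) |>
    filter(.data$iend >= .data$istart) |>
    select(seqid = "seqid", start = "istart", end = "iend",
           strand = "strand")
}

#' Extract short-intron (SI) regions from annotation
#'
#' Identifies introns of total length at most `max_intron_len` (65 bp) and
#' returns, for each, the putatively neutral SI region: 1-based positions
#' 8..30 from the intron's 5' end (strand-aware), i.e. up to 23 sites.
#' A candidate is excluded if its SI region overlaps an exon, an intron
#' longer than 65 bp, or the non-SI portion of another short intron.
#' Identical genomic intervals arising from alternative transcripts are
#' de-duplicated to one copy (the number removed is reported in the
#' `"n_duplicates"` attribute).
#'
#' @param gff Path to a GFF3 file, or a data frame of GFF3 fields.
#'   Introns are taken from explicit `intron` features when present,
#'   otherwise reconstructed from the exon gaps of each transcript.
#' @param genome A named `DNAStringSet` (or path to a FASTA file) holding
#'   the reference sequence.
#' @param max_intron_len Maximum intron length retained (default 65).
#' @param si_from,si_to SI region bounds, 1-based inclusive positions from
#'   the intron 5' end (defaults 8 and 30).
#' @return A tibble of SI regions with 0-based half-open coordinates:
#'   `intron_id`, `chrom`, `start`, `end` (SI region), `strand`,
#'   `intron_start`, `intron_end`, `intron_length`, `si_length`, `seq`
#'   (5'->3', reverse-complemented on the minus strand), `gc`.
#' @export
extract_short_introns <- function(gff, genome, max_intron_len = 65L,
                                  si_from = 8L, si_to = 30L) {
  features <- read_gff3_features(gff)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  introns <- derive_introns(features) |>
    mutate(len = .data$end - .data$start + 1L) |>
    dplyr::distinct(.data$seqid, .data$start, .data$end, .data$strand,
                    .keep_all = TRUE)
  short <- introns |> filter(.data$len <= max_intron_len,
                             .data$len >= si_from)
  long <- introns |> filter(.data$len > max_intron_len)

  # SI region in genome coordinates (1-based inclusive), strand-aware
  si <- short |>
    mutate(
      hi = pmin(si_to, .data$len),
      g_start = ifelse(.data$strand == "-",
                       .data$end - .data$hi + 1L,
                       .data$start + si_from - 1L),
      g_end = ifelse(.data$strand == "-",
                     .data$end - si_from + 1L,
                     .data$start + .data$hi - 1L)
    )

  n_dup_total <- nrow(introns) - nrow(dplyr::distinct(
    introns, .data$seqid, .data$start, .data$end, .data$strand))

  si_gr <- GenomicRanges::GRanges(
    si$seqid, IRanges::IRanges(si$g_start, si$g_end), strand = "*"
  )
  exons <- features |> filter(.data$type == "exon")
  excl <- list(
    GenomicRanges::GRanges(exons$seqid,
                           IRanges::IRanges(exons$start, exons$end)),
    GenomicRanges::GRanges(long$seqid,
                           IRanges::IRanges(long$start, long$end))
  )
  # non-SI portions of every short intron (5' positions 1..7 and 31..len)
  flank5 <- si |> filter(si_from > 1L) |>
    mutate(
      f_start = ifelse(.data$strand == "-", .data$g_end + 1L, .data$start),
      f_end = ifelse(.data$strand == "-", .data$end, .data$g_start - 1L)
    )
  flank3 <- si |> filter(.data$len > .data$hi) |>
    mutate(
      f_start = ifelse(.data$strand == "-", .data$start, .data$g_end + 1L),
      f_end = ifelse(.data$strand == "-", .data$g_start - 1L, .data$end)
    )
  flanks <- bind_rows(flank5, flank3)
  if (nrow(flanks) > 0) {
    excl <- c(excl, list(GenomicRanges::GRanges(
      flanks$seqid, IRanges::IRanges(flanks$f_start, flanks$f_end))))
  }
  excl_gr <- suppressWarnings(do.call(c, excl))
  hits <- GenomicRanges::countOverlaps(si_gr, excl_gr, ignore.strand = TRUE)
  si <- si[hits == 0L, , drop = FALSE]

  missing_chrom <- setdiff(unique(si$seqid), names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf("Chromosome `%s` in annotation but not in the genome.",
                  missing_chrom[1]))
  }
  if (any(si$g_end > Biostrings::width(genome)[match(si$seqid,
                                                     names(genome))])) {
    abort("Annotation coordinates extend beyond the reference sequence.")
  }
  seqs <- as.character(Biostrings::subseq(
    genome[si$seqid], start = si$g_start, end = si$g_end
  ))
  minus <- si$strand == "-"
  seqs[minus] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus]))
  )

  out <- tibble(
    intron_id = sprintf("%s:%d-%d:%s", si$seqid, si$start - 1L, si$end,
                        si$strand),
    chrom = si$seqid,
    start = si$g_start - 1L,
    end = si$g_end,
    strand = si$strand,
    intron_start = si$start - 1L,
    intron_end = si$end,
    intron_length = si$len,
    si_length = si$g_end - si$g_start + 1L,
    seq = unname(seqs),
    gc = compute_gc(unname(seqs))
  )
  attr(out, "n_duplicates") <- n_dup_total
  out
}

#' Read whole-genome-alignment columns in the tab-separated WGA-BED layout
#'
#' One row per alignment column; for each of the three species (focal `a`,
#' second species `b`, outgroup `out`) the columns
#' `chrom_*, start_*, end_*, strand_*, allele_*` give the 0-based
#' half-open single-base position and the reference allele (lowercase =
#' soft-masked; `-` = gap).
#'
#' @param path Path to the tab-separated file (no header or header with
#'   these exact names).
#' @return A tibble of alignment columns.
#' @export
read_wga_bed <- function(path) {
  cols <- as.vector(outer(c("chrom", "start", "end", "strand", "allele"),
                          c("a", "b", "out"),
                          function(x, y) paste(x, y, sep = "_")))
  first <- readr::read_lines(path, n_max = 1L)
  has_header <- grepl("chrom_a", first, fixed = TRUE)
  readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else cols,
    skip = 0L,
    show_col_types = FALSE,
    col_types = readr::cols(
      .default = readr::col_character(),
      start_a = readr::col_integer(), end_a = readr::col_integer(),
      start_b = readr::col_integer(), end_b = readr::col_integer(),
      start_out = readr::col_integer(), end_out = readr::col_integer()
    )
  )
}

#' Homologous SI sites from whole-genome-alignment columns
#'
#' Keeps the alignment columns whose position falls inside an SI region in
#' BOTH species and whose three reference alleles are all present (no gap
#' or `N`).  Columns missing a species are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param si_a,si_b SI tables from [extract_short_introns()] for the two
#'   species (coordinates of species `a` and `b` respectively).
#' @param wga Alignment-column tibble from [read_wga_bed()].
#' @return A site tibble: one row per homologous SI site with per-species
#'   coordinates, intron ids, and the three reference alleles (case
#'   preserved; lowercase marks soft-masking).
#' @export
intersect_homologous_sites <- function(si_a, si_b, wga) {
  complete <- !is.na(wga$chrom_a) & !is.na(wga$chrom_b) &
    !is.na(wga$chrom_out) & wga$chrom_a != "." & wga$chrom_b != "." &
    wga$chrom_out != "."
  n_skipped <- sum(!complete)
  wga <- wga[complete, , drop = FALSE]

  locate <- function(si, chrom, pos0) {
    # pos0: 0-based position; si start/end are 0-based half-open
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L))
    s <- GenomicRanges::GRanges(si$chrom,
                                IRanges::IRanges(si$start + 1L, si$end))
    hit <- GenomicRanges::findOverlaps(q, s, select = "first")
    hit
  }
  hit_a <- locate(si_a, wga$chrom_a, wga$start_a)
  hit_b <- locate(si_b, wga$chrom_b, wga$start_b)
  ok_allele <- function(x) !is.na(x) & toupper(x) %in% BASES
  keep <- !is.na(hit_a) & !is.na(hit_b) &
    ok_allele(wga$allele_a) & ok_allele(wga$allele_b) &
    ok_allele(wga$allele_out)
  out <- tibble(
    site_id = paste0(wga$chrom_a[keep], ":", wga$start_a[keep]),
    intron_id_a = si_a$intron_id[hit_a[keep]],
    intron_id_b = si_b$intron_id[hit_b[keep]],
    chrom_a = wga$chrom_a[keep], pos_a = wga$start_a[keep],
    chrom_b = wga$chrom_b[keep], pos_b = wga$start_b[keep],
    chrom_out = wga$chrom_out[keep], pos_out = wga$start_out[keep],
    allele_a = wga$allele_a[keep],
    allele_b = wga$allele_b[keep],
    allele_out = wga$allele_out[keep]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

read_bed3 <- function(x) {
  if (is.data.frame(x)) return(as_tibble(x))
  readr::read_tsv(x, col_names = c("chrom", "start", "end"),
                  col_types = "cii", comment = "#",
                  show_col_types = FALSE)
}

in_bed <- function(chrom, pos0, bed) {
  if (nrow(bed) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, pos0 + 1L))
  s <- GenomicRanges::GRanges(bed$chrom,
                              IRanges::IRanges(bed$start + 1L, bed$end))
  GenomicRanges::countOverlaps(q, s) > 0
}

#' Apply the SI site filters
#'
#' Retains sites that are (i) autosomal in both species, (ii) not
#' soft-masked (lowercase) in any of the three reference alleles,
#' (iii) not overlapping an indel, (iv) passing the variant-call quality
#' threshold (sites without a variant record pass by default), and
#' (v) outside non-crossover regions in both species.  In polymorphism
#' mode, sites with any missing ingroup allele are also dropped.
#' Filtering is idempotent: applying it twice gives the same result.
#'
#' @param sites Site tibble from [intersect_homologous_sites()], optionally
#'   carrying an `ingroup_alleles` column (string of `n` haploid calls).
#' @param autosomes_a,autosomes_b Chromosome names counted as autosomal in
#'   each species (`NULL` = no autosome filter).
#' @param exclude_a,exclude_b BED tables or paths (0-based half-open) of
#'   regions to exclude in each species' coordinates (e.g. non-crossover
#'   regions); lists of several BEDs are allowed.
#' @param indel_overlap Optional logical vector or column name flagging
#'   sites overlapping indels.
#' @param qual Optional tibble `chrom, pos, qual` of variant-record
#'   qualities in species-`a` coordinates (0-based positions).
#' @param qual_threshold Minimum QUAL retained where a record exists
#'   (default 30).
#' @param mode `"divergence"` keeps sites with missing polymorphism data;
#'   `"polymorphism"` drops them.
#' @return The filtered site tibble, with an `"attrition"` attribute
#'   recording per-filter removal counts.
#' @export
apply_site_filters <- function(sites,
                               autosomes_a = NULL, autosomes_b = NULL,
                               exclude_a = NULL, exclude_b = NULL,
                               indel_overlap = NULL,
                               qual = NULL, qual_threshold = 30,
                               mode = c("divergence", "polymorphism")) {
  mode <- match.arg(mode)
  attrition <- list()
  drop_step <- function(sites, keep, label) {
    attrition[[label]] <<- sum(!keep)
    sites[keep, , drop = FALSE]
  }

  if (!is.null(autosomes_a)) {
    sites <- drop_step(sites, sites$chrom_a %in% autosomes_a &
                         sites$chrom_b %in% (autosomes_b %||% autosomes_a),
                       "non_autosomal")
  }
  masked <- sites$allele_a != toupper(sites$allele_a) |
    sites$allele_b != toupper(sites$allele_b) |
    sites$allele_out != toupper(sites$allele_out)
  sites <- drop_step(sites, !masked, "soft_masked")
  if (!is.null(indel_overlap)) {
    flag <- if (is.character(indel_overlap) && length(indel_overlap) == 1L) {
      sites[[indel_overlap]]
    } else {
      indel_overlap[seq_len(nrow(sites))]
    }
    sites <- drop_step(sites, !flag, "indel_overlap")
  }
  if (!is.null(qual)) {
    q <- as_tibble(qual)
    key_site <- paste0(sites$chrom_a, ":", sites$pos_a)
    key_q <- paste0(q$chrom, ":", q$pos)
    qv <- q$qual[match(key_site, key_q)]
    sites <- drop_step(sites, is.na(qv) | qv >= qual_threshold, "low_qual")
  }
  for (side in c("a", "b")) {
    beds <- list(exclude_a, exclude_b)[[match(side, c("a", "b"))]]
    if (is.null(beds)) next
    if (!is.list(beds) || is.data.frame(beds)) beds <- list(beds)
    for (bi in seq_along(beds)) {
      bed <- read_bed3(beds[[bi]])
      inside <- in_bed(sites[[paste0("chrom_", side)]],
                       sites[[paste0("pos_", side)]], bed)
      sites <- drop_step(sites, !inside,
                         paste0("excluded_region_", side, "_", bi))
    }
  }
  if (mode == "polymorphism" && "ingroup_alleles" %in% names(sites)) {
    miss <- stringr::str_detect(toupper(sites$ingroup_alleles), "[^ACGT]")
    sites <- drop_step(sites, !miss, "missing_polymorphism_data")
  }
  attr(sites, "attrition") <- tibble(
    filter = names(attrition),
    removed = as.integer(unlist(attrition))
  )
  sites
}
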