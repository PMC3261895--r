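#' Specification of a planted repeat family
#'
#' A family is a random master unit copied `copy_number` times into the
#' genome. Divergence is modeled as up to `max_divergence` biallelic
#' segregating sites shared by the family: each site has one alternate
#' base, and each copy carries the alternate allele at a random subset
#' of the sites. Any two copies therefore differ at no more than
#' `max_divergence` positions, so a family with `max_divergence <= m` is
#' guaranteed to be counted as one equivalence class at mismatch
#' tolerance m.
#'
#' @param unit_length repeat unit length in bp (must exceed
#'   `max_divergence`).
#' @param copy_number number of planted copies (>= 2).
#' @param max_divergence maximum pairwise substitutions between copies.
#' @param revcomp_copies if `TRUE`, each copy is planted on the reverse
#'   strand with probability 1/2.
#' @return A `repeat_spec`.
#' @export
repeat_spec <- function(unit_length, copy_number, max_divergence = 0L,
                        revcomp_copies = FALSE) {
  unit_length <- as.integer(unit_length)
  copy_number <- as.integer(copy_number)
  max_divergence <- as.integer(max_divergence)
  if (copy_number < 2) stop("copy_number must be >= 2")
  if (unit_length <= max_divergence)
    stop("unit_length must exceed max_divergence")
  structure(list(unit_length = unit_length, copy_number = copy_number,
                 max_divergence = max_divergence,
                 revcomp_copies = isTRUE(revcomp_copies)),
            class = "repeat_spec")
}

# one derived seed per named component, stable under feature addition
component_seed <- function(seed, component, i = 0L) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 9973 + i * 7919) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# place `count` intervals of length `len` uniformly in [1, L-len+1]
# (1-based starts), avoiding `occupied` (data.frame start,end half-open
# 0-based) -- returns 0-based starts or NULL if packing fails
place_intervals <- function(L, len, count, occupied, tries = 2000L) {
  starts <- integer(0)
  occ <- occupied
  for (i in seq_len(count)) {
    placed <- FALSE
    for (tr in seq_len(tries)) {
      s <- sample.int(L - len + 1L, 1L) - 1L
      e <- s + len
      if (nrow(occ) == 0 || all(e <= occ$start | s >= occ$end)) {
        occ <- rbind(occ, data.frame(start = s, end = e))
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  starts
}

#' Generate a synthetic genome with planted repeat families
#'
#' The background is i.i.d. uniform A/C/G/T; each repeat family plants
#' `copy_number` diverged copies of one random master unit at uniform
#' non-overlapping locations (copies of different families do not
#' overlap either); optional N-gaps are placed in the remaining space.
#' A truth table records every planted copy. Output is a deterministic
#' function of `seed`: each component (background, units, placement,
#' mutation, gaps) draws from its own derived stream.
#'
#' @param length integer vector of contig lengths (one contig per
#'   element, named `chr1`, `chr2`, ...).
#' @param repeat_specs list of [repeat_spec()]s.
#' @param gaps optional `list(count =, length =)` of N-gaps to plant.
#' @param seed integer seed.
#' @return A list with `ref` (a [reference_sequence()]), `truth`
#'   (data.frame: family, copy, contig, start, end, strand, divergence)
#'   and `gaps` (data.frame of planted N intervals).
#' @export
generate_genome <- function(length, repeat_specs = list(), gaps = NULL,
                            seed = 1L) {
  lens <- as.integer(length)
  if (any(lens < 1)) stop("contig lengths must be positive")
  if (inherits(repeat_specs, "repeat_spec")) repeat_specs <- list(repeat_specs)
  planted <- sum(vapply(repeat_specs, function(s)
    s$unit_length * s$copy_number, numeric(1)))
  if (planted >= sum(lens)) stop("infeasible packing: planted span >= genome")
  nm <- paste0("chr", seq_along(lens))

  set.seed(component_seed(seed, "background"))
  chars <- lapply(lens, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(chars) <- nm

  occupied <- lapply(lens, function(L) data.frame(start = integer(0),
                                                  end = integer(0)))
  names(occupied) <- nm

  gap_df <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  if (!is.null(gaps)) {
    set.seed(component_seed(seed, "gaps"))
    for (i in seq_len(gaps$count)) {
      ctg <- sample(seq_along(lens), 1L, prob = lens)
      s <- place_intervals(lens[ctg], gaps$length, 1L, occupied[[ctg]])
      if (is.null(s)) stop("infeasible packing: cannot place gap")
      occupied[[ctg]] <- rbind(occupied[[ctg]],
                               data.frame(start = s, end = s + gaps$length))
      chars[[ctg]][(s + 1L):(s + gaps$length)] <- "N"
      gap_df <- rbind(gap_df, data.frame(contig = nm[ctg], start = s,
                                         end = s + gaps$length,
                                         stringsAsFactors = FALSE))
    }
  }

  truth <- list()
  for (f in seq_along(repeat_specs)) {
    sp <- repeat_specs[[f]]
    set.seed(component_seed(seed, "units", f))
    master <- strsplit(random_dna(sp$unit_length), "")[[1]]
    sites <- if (sp$max_divergence > 0)
      sample.int(sp$unit_length, sp$max_divergence) else integer(0)
    alt <- vapply(sites, function(s)
      sample(setdiff(c("A", "C", "G", "T"), master[s]), 1L), character(1))

    set.seed(component_seed(seed, "placement", f))
    ctgs <- integer(0)
    starts <- integer(0)
    for (cp in seq_len(sp$copy_number)) {
      ctg <- sample(seq_along(lens), 1L, prob = lens)
      s <- place_intervals(lens[ctg], sp$unit_length, 1L, occupied[[ctg]])
      if (is.null(s))
        stop("infeasible packing: cannot place copy ", cp, " of family ", f)
      occupied[[ctg]] <- rbind(occupied[[ctg]],
                               data.frame(start = s,
                                          end = s + sp$unit_length))
      ctgs <- c(ctgs, ctg)
      starts <- c(starts, s)
    }

    set.seed(component_seed(seed, "mutation", f))
    for (cp in seq_len(sp$copy_number)) {
      copy <- master
      carried <- if (length(sites) > 0)
        which(stats::runif(length(sites)) < 0.5) else integer(0)
      copy[sites[carried]] <- alt[carried]
      strand <- "+"
      if (sp$revcomp_copies && stats::runif(1) < 0.5) {
        copy <- strsplit(cpp_revcomp(paste(copy, collapse = "")), "")[[1]]
        strand <- "-"
      }
      s <- starts[cp]
      chars[[ctgs[cp]]][(s + 1L):(s + sp$unit_length)] <- copy
      truth[[length(truth) + 1L]] <- data.frame(
        family = f, copy = cp, contig = nm[ctgs[cp]], start = s,
        end = s + sp$unit_length, strand = strand,
        divergence = length(carried), unit_length = sp$unit_length,
        copy_number = sp$copy_number, stringsAsFactors = FALSE)
    }
  }

  seqs <- vapply(chars, paste, character(1), collapse = "")
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(family = integer(0), copy = integer(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), divergence = integer(0),
               unit_length = integer(0), copy_number = integer(0))
  list(ref = reference_sequence(seqs), truth = truth, gaps = gap_df,
       seed = seed)
}

#' Generate a gene annotation over a synthetic genome
#'
#' Genes get 1-5 exons of 80-300 bp. Classes with placement
#' `"background"` draw exons from repeat-free, gap-free sequence;
#' classes with placement `"repeat"` put one exon exactly on a planted
#' repeat copy (cycling over copies), modelling multi-copy families such
#' as clustered rRNAs.
#'
#' @param genome result of [generate_genome()].
#' @param classes data.frame with columns `class`, `n`, `placement`
#'   (`"background"` or `"repeat"`).
#' @param seed integer seed.
#' @return A `gene_models` data.frame (as from [project_exons()]).
#' @export
generate_annotation <- function(genome,
                                classes = data.frame(
                                  class = c("protein_coding", "rRNA"),
                                  n = c(5L, 2L),
                                  placement = c("background", "repeat"),
                                  stringsAsFactors = FALSE),
                                seed = 1L) {
  ref <- genome$ref
  set.seed(component_seed(seed, "annotation"))
  avoid <- rbind(
    data.frame(contig = genome$truth$contig, start = genome$truth$start,
               end = genome$truth$end, stringsAsFactors = FALSE),
    genome$gaps[, c("contig", "start", "end")]
  )
  rows <- list()
  gi <- 0L
  rep_rows <- genome$truth
  rep_cursor <- 0L
  for (ci in seq_len(nrow(classes))) {
    for (g in seq_len(classes$n[ci])) {
      gi <- gi + 1L
      id <- sprintf("gene%03d", gi)
      if (classes$placement[ci] == "repeat") {
        if (nrow(rep_rows) == 0) stop("no planted repeats to place genes on")
        rep_cursor <- rep_cursor %% nrow(rep_rows) + 1L
        rr <- rep_rows[rep_cursor, ]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = id, class = classes$class[ci], contig = rr$contig,
          start = rr$start, end = rr$end, strand = "+",
          stringsAsFactors = FALSE)
      } else {
        n_ex <- sample(1:5, 1L)
        ctg <- sample(seq_along(ref$names), 1L, prob = ref$lengths)
        occ <- avoid[avoid$contig == ref$names[ctg],
                     c("start", "end"), drop = FALSE]
        for (e in seq_len(n_ex)) {
          len <- sample(80:300, 1L)
          s <- place_intervals(ref$lengths[ctg], len, 1L, occ)
          if (is.null(s)) stop("infeasible packing: cannot place exon")
          occ <- rbind(occ, data.frame(start = s, end = s + len))
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = id, class = classes$class[ci],
            contig = ref$names[ctg], start = s, end = s + len,
            strand = "+", stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  project_exons(df, ref = ref)
}
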