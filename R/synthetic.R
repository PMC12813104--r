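#' Specify a host species' base community
#'
#' Describes the algae-associated community simulated for one host species:
#' how many OTUs it carries, the spread of their log-normal relative
#' abundances, and how much of the 16S read mass is hijacked by chloroplast
#' sequences amplified from the host plastid genome. Chloroplast load is
#' strongly species-specific in macroalgae (red algae can reach ~40% of
#' reads, brown and green algae more typically 5--10%), which is why it is a
#' per-species parameter rather than a global one.
#'
#' @param name species label.
#' @param n_otus total number of OTUs, chloroplast OTUs included.
#' @param abundance_log_mean,abundance_log_sd log-normal parameters of the
#'   bacterial relative-abundance distribution (dimensionless).
#' @param chloroplast_fraction proportion of total read mass assigned to
#'   chloroplast OTUs, in `[0, 1)`.
#' @param n_chloroplast_otus number of distinct chloroplast OTUs carrying
#'   that mass (ignored when `chloroplast_fraction` is 0).
#' @return an object of class `species_spec`.
#' @seealso [default_species_specs()], [generate_base_profile()]
#' @export
species_spec <- function(name, n_otus, abundance_log_mean = 0,
                         abundance_log_sd = 1.5,
                         chloroplast_fraction = 0,
                         n_chloroplast_otus = 0L) {
  stopifnot(is_label(name))
  if (!is_number(n_otus) || n_otus < 1) {
    stop("`n_otus` must be a positive integer", call. = FALSE)
  }
  if (!is_number(chloroplast_fraction) ||
      chloroplast_fraction < 0 || chloroplast_fraction >= 1) {
    stop("`chloroplast_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (chloroplast_fraction == 0) n_chloroplast_otus <- 0L
  if (n_chloroplast_otus > n_otus) {
    stop("`n_chloroplast_otus` cannot exceed `n_otus`", call. = FALSE)
  }
  if (chloroplast_fraction > 0 && n_chloroplast_otus < 1) {
    stop("a positive `chloroplast_fraction` needs at least one chloroplast OTU",
         call. = FALSE)
  }
  if (!is_number(abundance_log_sd) || abundance_log_sd < 0) {
    stop("`abundance_log_sd` must be non-negative", call. = FALSE)
  }
  structure(
    list(name = name, n_otus = as.integer(n_otus),
         abundance_log_mean = abundance_log_mean,
         abundance_log_sd = abundance_log_sd,
         chloroplast_fraction = chloroplast_fraction,
         n_chloroplast_otus = as.integer(n_chloroplast_otus)),
    class = "species_spec"
  )
}

#' Specify a DNA-extraction kit's behaviour
#'
#' Captures the downstream-visible behaviour of one extraction kit: a
#' systematic per-OTU capture bias (log-normal multiplier spread), random OTU
#' dropout, the mass of kit-reagent contaminant DNA it injects, the mean
#' template mass it recovers (lower template means reagent contaminants make
#' up a larger share of the library), the PCR dilution factor its extracts
#' require, and the bench-side attributes (protocol simplicity, cost per
#' sample) used in ranking. Optional QC means (`din`, `a260_280`, `a260_230`)
#' parameterise the simulated quality-control table; `din = NA` emulates a
#' kit whose extracts are too degraded or dilute for DIN measurement.
#'
#' @param name kit label.
#' @param capture_bias_sd log-scale standard deviation of the per-OTU capture
#'   multipliers (0 = unbiased).
#' @param dropout_rate proportion of OTUs the kit fails to capture at all, in
#'   `[0, 1)`.
#' @param contaminant_load_ng mass of reagent-borne contaminant DNA (ng).
#' @param mean_template_ng mean recovered template mass per sample (ng).
#' @param dilution_factor one of `"1"`, `"10"`, `"100"`, `"failed"`.
#' @param simplicity protocol simplicity score, integer 1 (simplest) to 5.
#' @param cost_per_sample cost per extracted sample (currency units).
#' @param din mean DNA integrity number (1--10), or `NA` if unmeasurable.
#' @param a260_280,a260_230 mean absorbance purity ratios.
#' @param chloroplast_affinity multiplier (>= 0) on the chloroplast OTU mass
#'   captured by this kit, applied before renormalisation; kits genuinely
#'   differ in how much host plastid DNA they co-extract, which is what makes
#'   chloroplast load a kit-ranking criterion.
#' @return an object of class `kit_spec`.
#' @seealso [default_kit_specs()], [apply_kit_bias()], [spike_contaminants()]
#' @export
kit_spec <- function(name, capture_bias_sd = 0.3, dropout_rate = 0.05,
                     contaminant_load_ng = 1, mean_template_ng = 30,
                     dilution_factor = "1", simplicity = 1L,
                     cost_per_sample = 5, din = 4, a260_280 = 1.85,
                     a260_230 = 1.5, chloroplast_affinity = 1) {
  stopifnot(is_label(name))
  if (!is_number(capture_bias_sd) || capture_bias_sd < 0) {
    stop("`capture_bias_sd` must be non-negative", call. = FALSE)
  }
  if (!is_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (!is_number(contaminant_load_ng) || contaminant_load_ng < 0) {
    stop("`contaminant_load_ng` must be non-negative", call. = FALSE)
  }
  if (!is_number(mean_template_ng) || mean_template_ng < 0) {
    stop("`mean_template_ng` must be non-negative", call. = FALSE)
  }
  dilution_factor <- as.character(dilution_factor)
  if (!dilution_factor %in% DILUTION_LEVELS) {
    stop("`dilution_factor` must be one of ",
         paste(DILUTION_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (!is_number(simplicity) || !simplicity %in% 1:5) {
    stop("`simplicity` must be an integer in 1..5", call. = FALSE)
  }
  if (!is_number(cost_per_sample) || cost_per_sample <= 0) {
    stop("`cost_per_sample` must be positive", call. = FALSE)
  }
  if (!is_number(chloroplast_affinity) || chloroplast_affinity < 0) {
    stop("`chloroplast_affinity` must be non-negative", call. = FALSE)
  }
  structure(
    list(name = name, capture_bias_sd = capture_bias_sd,
         dropout_rate = dropout_rate,
         contaminant_load_ng = contaminant_load_ng,
         mean_template_ng = mean_template_ng,
         dilution_factor = dilution_factor,
         simplicity = as.integer(simplicity),
         cost_per_sample = cost_per_sample,
         din = din, a260_280 = a260_280, a260_230 = a260_230,
         chloroplast_affinity = chloroplast_affinity),
    class = "kit_spec"
  )
}

#' Default host-species specifications
#'
#' Three macroalgae hosts spanning the red/brown/green groups. The red alga
#' carries a heavy chloroplast load (35% of reads) and the richest community;
#' the brown and green algae sit at 8% chloroplast with smaller communities.
#'
#' @return named list of [species_spec()] objects.
#' @export
default_species_specs <- function() {
  specs <- list(
    species_spec("P_stenogona", n_otus = 250, abundance_log_sd = 1.5,
                 chloroplast_fraction = 0.35, n_chloroplast_otus = 12L),
    species_spec("S_japonica", n_otus = 150, abundance_log_sd = 1.5,
                 chloroplast_fraction = 0.08, n_chloroplast_otus = 6L),
    species_spec("U_lactuca", n_otus = 200, abundance_log_sd = 1.5,
                 chloroplast_fraction = 0.08, n_chloroplast_otus = 8L)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Default extraction-kit specifications
#'
#' Six kits mirroring the behaviour of widely used commercial products:
#' simplicity scores and per-sample costs follow published vendor figures,
#' template yields and reagent contaminant loads are set so that
#' low-yield kits show elevated contaminant proportions, and dilution
#' factors encode PCR-inhibitor carry-over (with `"100"` the worst measurable
#' outcome). One kit (`QiaSto`) has `din = NA`, emulating extracts on which
#' DNA-integrity measurement fails.
#'
#' @return named list of [kit_spec()] objects.
#' @export
default_kit_specs <- function() {
  specs <- list(
    kit_spec("PowSoi", contaminant_load_ng = 0.5, mean_template_ng = 40,
             dilution_factor = "1", simplicity = 1L, cost_per_sample = 9.80,
             din = 3.0, a260_280 = 1.85, a260_230 = 1.4,
             chloroplast_affinity = 1.3),
    kit_spec("PowFec", contaminant_load_ng = 1.5, mean_template_ng = 35,
             dilution_factor = "1", simplicity = 1L, cost_per_sample = 9.66,
             din = 3.0, a260_280 = 1.85, a260_230 = 1.4,
             chloroplast_affinity = 1.3),
    kit_spec("QiaSto", contaminant_load_ng = 0.5, mean_template_ng = 5,
             dilution_factor = "1", simplicity = 1L, cost_per_sample = 7.68,
             din = NA_real_, a260_280 = 1.9, a260_230 = 2.1,
             chloroplast_affinity = 0.7),
    kit_spec("BT", contaminant_load_ng = 1.5, mean_template_ng = 60,
             dilution_factor = "100", simplicity = 2L, cost_per_sample = 4.48,
             din = 3.5, a260_280 = 1.8, a260_230 = 1.3),
    kit_spec("Thermo", contaminant_load_ng = 1.5, mean_template_ng = 20,
             dilution_factor = "1", simplicity = 1L, cost_per_sample = 3.90,
             din = 4.0, a260_280 = 1.85, a260_230 = 1.5,
             chloroplast_affinity = 0.7),
    kit_spec("MonNEB", contaminant_load_ng = 0.5, mean_template_ng = 50,
             dilution_factor = "10", simplicity = 2L, cost_per_sample = 10.78,
             din = 6.5, a260_280 = 1.9, a260_230 = 1.6)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

# Static order -> (phylum, class) map used when fabricating bacterial
# lineages; orders are typical marine epiphyte taxa so taxonomic summaries
# look like real amplicon data.
.bacterial_orders <- list(
  Flavobacteriales   = c("Bacteroidota", "Bacteroidia"),
  Rhodobacterales    = c("Proteobacteria", "Alphaproteobacteria"),
  Caulobacterales    = c("Proteobacteria", "Alphaproteobacteria"),
  Sphingomonadales   = c("Proteobacteria", "Alphaproteobacteria"),
  Alteromonadales    = c("Proteobacteria", "Gammaproteobacteria"),
  Thiotrichales      = c("Proteobacteria", "Gammaproteobacteria"),
  Granulosicoccales  = c("Proteobacteria", "Gammaproteobacteria"),
  Vibrionales        = c("Proteobacteria", "Gammaproteobacteria"),
  Oceanospirillales  = c("Proteobacteria", "Gammaproteobacteria"),
  Cellvibrionales    = c("Proteobacteria", "Gammaproteobacteria"),
  Verrucomicrobiales = c("Verrucomicrobiota", "Verrucomicrobiae"),
  Planctomycetales   = c("Planctomycetota", "Planctomycetia")
)

# Reagent-contaminant genera: human-associated taxa recurrently reported in
# extraction-kit negative controls, suffixed "-like" so planted contaminants
# are recognisable in the emitted taxonomy and disjoint from the community
# label set.
.contaminant_genera <- data.frame(
  genus  = paste0(c("Staphylococcus", "Streptococcus", "Cutibacterium",
                    "Corynebacterium", "Micrococcus", "Escherichia",
                    "Pseudomonas", "Ralstonia"), "-like"),
  order  = c("Staphylococcales", "Lactobacillales", "Propionibacteriales",
             "Mycobacteriales", "Micrococcales", "Enterobacterales",
             "Pseudomonadales", "Burkholderiales"),
  phylum = c("Bacillota", "Bacillota", "Actinobacteriota", "Actinobacteriota",
             "Actinobacteriota", "Proteobacteria", "Proteobacteria",
             "Proteobacteria"),
  class  = c("Bacilli", "Bacilli", "Actinobacteria", "Actinobacteria",
             "Actinobacteria", "Gammaproteobacteria", "Gammaproteobacteria",
             "Gammaproteobacteria"),
  stringsAsFactors = FALSE
)

#' Generate a species' base community profile
#'
#' Draws log-normal relative abundances for the bacterial OTUs of one host
#' species, inserts `n_chloroplast_otus` OTUs whose order-level taxonomy is
#' the literal string `"Chloroplast"`, and renormalises so the chloroplast
#' OTUs jointly carry `chloroplast_fraction` of the read mass and the
#' bacterial OTUs the remainder.
#'
#' @param spec a [species_spec()].
#' @param seed integer seed; the same seed reproduces the profile exactly.
#' @return list with `proportions` (named vector summing to 1), `taxonomy`
#'   (data.frame with columns `otu_id`, `domain` .. `genus`), and
#'   `chloroplast_otu_ids`.
#' @examples
#' prof <- generate_base_profile(species_spec("demo", 20,
#'   chloroplast_fraction = 0.2, n_chloroplast_otus = 2), seed = 1)
#' sum(prof$proportions)
#' @export
generate_base_profile <- function(spec, seed) {
  stopifnot(inherits(spec, "species_spec"))
  n_chl <- spec$n_chloroplast_otus
  n_bact <- spec$n_otus - n_chl
  if (n_bact < 1) stop("species must have at least one bacterial OTU",
                       call. = FALSE)
  with_seed(seed, {
    bact_raw <- stats::rlnorm(n_bact, spec$abundance_log_mean,
                              spec$abundance_log_sd)
    bact_ids <- sprintf("%s_OTU%04d", spec$name, seq_len(n_bact))
    props <- bact_raw / sum(bact_raw) * (1 - spec$chloroplast_fraction)
    names(props) <- bact_ids

    orders <- sample(names(.bacterial_orders), n_bact, replace = TRUE)
    tax <- data.frame(
      otu_id = bact_ids,
      domain = "Bacteria",
      phylum = vapply(orders, function(o) .bacterial_orders[[o]][1], ""),
      class  = vapply(orders, function(o) .bacterial_orders[[o]][2], ""),
      order  = orders,
      family = sub("ales$", "aceae", orders),
      genus  = sprintf("%s_g%04d", sub("ales$", "", orders), seq_len(n_bact)),
      stringsAsFactors = FALSE, row.names = NULL
    )

    chl_ids <- character(0)
    if (n_chl > 0) {
      chl_ids <- sprintf("%s_CHLORO%02d", spec$name, seq_len(n_chl))
      chl_raw <- stats::rlnorm(n_chl, 0, 1)
      chl_props <- chl_raw / sum(chl_raw) * spec$chloroplast_fraction
      names(chl_props) <- chl_ids
      props <- c(props, chl_props)
      tax <- rbind(tax, data.frame(
        otu_id = chl_ids, domain = "Bacteria", phylum = "Cyanobacteria",
        class = "Cyanobacteriia", order = "Chloroplast", family = "",
        genus = "", stringsAsFactors = FALSE
      ))
    }
    list(proportions = props, taxonomy = tax, chloroplast_otu_ids = chl_ids)
  })
}

#' Apply a kit's systematic capture bias to a community profile
#'
#' Multiplies each OTU's relative abundance by a log-normal capture
#' multiplier (log-sd `capture_bias_sd`), zeroes a random `dropout_rate`
#' fraction of OTUs, and renormalises. The multiplier draw is a property of
#' the kit, not of the replicate: all technical replicates extracted with the
#' same kit share the same distortion, which is what makes the bias
#' detectable as a kit effect downstream.
#'
#' @param proportions named proportion vector summing to 1.
#' @param kit a [kit_spec()].
#' @param seed integer seed.
#' @return list with `proportions` (renormalised), `multipliers` (per-OTU,
#'   dropout not included) and `dropped_otu_ids`.
#' @export
apply_kit_bias <- function(proportions, kit, seed) {
  stopifnot(inherits(kit, "kit_spec"))
  check_proportions(proportions)
  n <- length(proportions)
  with_seed(seed, {
    mult <- stats::rlnorm(n, 0, kit$capture_bias_sd)
    names(mult) <- names(proportions)
    out <- proportions * mult
    n_drop <- round(kit$dropout_rate * n)
    dropped <- character(0)
    if (n_drop > 0) {
      dropped <- sample(names(proportions), n_drop)
      out[dropped] <- 0
    }
    if (sum(out) <= 0) {
      stop("kit bias removed all community mass", call. = FALSE)
    }
    list(proportions = out / sum(out), multipliers = mult,
         dropped_otu_ids = dropped)
  })
}

#' Mix kit-reagent contaminants into a community profile
#'
#' Implements the template-dilution mechanism by which reagent contaminants
#' enter libraries: the contaminant profile receives a mass fraction
#' `contaminant_load_ng / (contaminant_load_ng + mean_template_ng)`, so kits
#' recovering less template DNA show proportionally more contamination. The
#' rule is deterministic; randomness enters only at read sampling.
#'
#' @param proportions named community proportions summing to 1.
#' @param kit a [kit_spec()] supplying load and template mass.
#' @param contaminant_profile named contaminant proportions summing to 1.
#' @return mixed, renormalised proportion vector over the union of supports.
#' @export
spike_contaminants <- function(proportions, kit, contaminant_profile) {
  stopifnot(inherits(kit, "kit_spec"))
  check_proportions(proportions)
  check_proportions(contaminant_profile)
  load <- kit$contaminant_load_ng
  template <- kit$mean_template_ng
  if (load == 0 && template == 0) {
    stop("contaminant load and template mass cannot both be zero",
         call. = FALSE)
  }
  f <- load / (load + template)
  mixed <- c(proportions * (1 - f), contaminant_profile * f)
  # overlapping supports (unusual) are summed
  tapply_sum <- tapply(mixed, names(mixed), sum)
  out <- as.vector(tapply_sum)[match(unique(names(mixed)), names(tapply_sum))]
  names(out) <- unique(names(mixed))
  out
}

#' Draw sequencing read counts from a community profile
#'
#' Multinomial read sampling at a fixed depth: the simplest model under which
#' observed relative abundances are unbiased for the underlying proportions.
#'
#' @param proportions named proportions summing to 1.
#' @param depth total read count (non-negative integer).
#' @param seed integer seed.
#' @return named integer count vector summing to `depth`.
#' @export
sample_counts <- function(proportions, depth, seed) {
  check_proportions(proportions)
  if (!is_number(depth) || depth < 0 || depth != round(depth)) {
    stop("`depth` must be a non-negative integer", call. = FALSE)
  }
  if (depth == 0) {
    return(stats::setNames(integer(length(proportions)), names(proportions)))
  }
  with_seed(seed, {
    counts <- stats::rmultinom(1, size = depth, prob = proportions)[, 1]
    stats::setNames(as.integer(counts), names(proportions))
  })
}

check_proportions <- function(p) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p) || any(p < 0)) {
    stop("proportions must be a non-negative numeric vector", call. = FALSE)
  }
  if (is.null(names(p)) || anyDuplicated(names(p))) {
    stop("proportions must carry unique OTU names", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' Generate a full synthetic kit-benchmark dataset
#'
#' Emulates the processed-table level of a kit-comparison study: for each
#' host species a base community (with species-specific chloroplast load) is
#' distorted by each kit's capture bias, mixed with that kit's reagent
#' contaminants in proportion to its template recovery, and sampled to
#' `depth` reads in `n_replicates` technical replicates. One no-input
#' "kitome" control per kit is drawn from the contaminant profile alone, at a
#' read depth proportional to the kit's contaminant load. A QC table
#' (concentration derived as template mass over a 60 uL elution volume with
#' multiplicative log-normal noise, DIN, purity ratios, PCR dilution factor)
#' and a ground-truth bundle accompany the tables.
#'
#' The RNG stream is split hierarchically by (species, kit, replicate), so
#' adding a kit or species leaves all other draws unchanged.
#'
#' @param species list of [species_spec()] objects.
#' @param kits list of [kit_spec()] objects.
#' @param n_replicates technical replicates per species x kit (default 3).
#' @param depth reads per sample (default 50000).
#' @param seed integer seed for the whole bundle.
#' @param conc_noise_sd log-sd of the multiplicative concentration noise.
#' @param n_contaminant_otus number of reagent-contaminant OTUs shared by all
#'   kits.
#' @param contaminant_log_sd log-sd of the contaminant profile.
#' @return an object of class `kitbench_dataset`: list with `otu` (integer
#'   matrix, samples x OTUs), `taxonomy`, `metadata` (sample records with QC
#'   fields), `kits` (kit profile data.frame), and `truth` (contaminant and
#'   chloroplast OTU ids, base proportions, per-kit bias multipliers, planted
#'   contaminant fractions).
#' @examples
#' ds <- generate_benchmark_dataset(
#'   species = default_species_specs()[1],
#'   kits = default_kit_specs()[1:2],
#'   n_replicates = 2, depth = 1000, seed = 1)
#' dim(ds$otu)
#' @export
generate_benchmark_dataset <- function(species = default_species_specs(),
                                       kits = default_kit_specs(),
                                       n_replicates = 3L, depth = 50000L,
                                       seed = 1L, conc_noise_sd = 0.1,
                                       n_contaminant_otus = 30L,
                                       contaminant_log_sd = 1) {
  if (length(species) == 0) stop("`species` must be non-empty", call. = FALSE)
  if (length(kits) == 0) stop("`kits` must be non-empty", call. = FALSE)
  stopifnot(all(vapply(species, inherits, TRUE, "species_spec")),
            all(vapply(kits, inherits, TRUE, "kit_spec")))
  if (!is_number(n_replicates) || n_replicates < 1) {
    stop("`n_replicates` must be >= 1", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)

  # shared reagent-contaminant profile, distinct taxonomic label set
  contam <- with_seed(derive_seed(seed, "contaminants"), {
    raw <- stats::rlnorm(n_contaminant_otus, 0, contaminant_log_sd)
    stats::setNames(raw / sum(raw),
                    sprintf("CONT_OTU%03d", seq_len(n_contaminant_otus)))
  })
  gi <- rep_len(seq_len(nrow(.contaminant_genera)), n_contaminant_otus)
  contam_tax <- data.frame(
    otu_id = names(contam),
    domain = "Bacteria",
    phylum = .contaminant_genera$phylum[gi],
    class  = .contaminant_genera$class[gi],
    order  = .contaminant_genera$order[gi],
    family = sub("ales$", "aceae", .contaminant_genera$order[gi]),
    genus  = .contaminant_genera$genus[gi],
    stringsAsFactors = FALSE
  )

  taxonomy <- contam_tax
  rows <- list()
  meta <- list()
  truth <- list(contaminant_otu_ids = names(contam),
                chloroplast_otu_ids = character(0),
                base_proportions = list(), per_kit_bias = list(),
                dropped_otu_ids = list(),
                contaminant_fraction = vapply(kits, function(k) {
                  k$contaminant_load_ng /
                    (k$contaminant_load_ng + k$mean_template_ng)
                }, 0),
                contaminant_profile = contam)
  names(truth$contaminant_fraction) <-
    vapply(kits, `[[`, "", "name")

  elution_volume <- 60  # uL
  kitome_reference_load <- 1.5  # ng load at which a kitome sequences to full depth

  for (sp in species) {
    base <- generate_base_profile(sp, derive_seed(seed, "base", sp$name))
    taxonomy <- rbind(taxonomy, base$taxonomy)
    truth$chloroplast_otu_ids <- c(truth$chloroplast_otu_ids,
                                   base$chloroplast_otu_ids)
    truth$base_proportions[[sp$name]] <- base$proportions
    truth$per_kit_bias[[sp$name]] <- list()
    truth$dropped_otu_ids[[sp$name]] <- list()

    for (kit in kits) {
      biased <- apply_kit_bias(base$proportions, kit,
                               derive_seed(seed, "bias", sp$name, kit$name))
      truth$per_kit_bias[[sp$name]][[kit$name]] <- biased$multipliers
      truth$dropped_otu_ids[[sp$name]][[kit$name]] <- biased$dropped_otu_ids
      kit_props <- biased$proportions
      if (kit$chloroplast_affinity != 1 &&
          length(base$chloroplast_otu_ids)) {
        kit_props[base$chloroplast_otu_ids] <-
          kit_props[base$chloroplast_otu_ids] * kit$chloroplast_affinity
        kit_props <- kit_props / sum(kit_props)
      }
      mixed <- spike_contaminants(kit_props, kit, contam)

      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_%s_rep%d", sp$name, kit$name, r)
        rows[[sid]] <- sample_counts(
          mixed, depth, derive_seed(seed, "counts", sp$name, kit$name, r))
        meta[[sid]] <- with_seed(
          derive_seed(seed, "qc", sp$name, kit$name, r), {
            template <- kit$mean_template_ng *
              stats::rlnorm(1, 0, conc_noise_sd)
            conc <- max(template / elution_volume *
                          stats::rlnorm(1, 0, conc_noise_sd), 0.1)
            din <- if (is.na(kit$din)) NA_real_ else
              min(10, max(1, kit$din + stats::rnorm(1, 0, 0.3)))
            data.frame(
              sample_id = sid, species = sp$name, kit = kit$name,
              replicate = r, is_control = FALSE,
              dna_conc = conc,
              input_mass = stats::runif(1, 1.5, 5),
              din = din,
              a260_280 = kit$a260_280 + stats::rnorm(1, 0, 0.05),
              a260_230 = kit$a260_230 + stats::rnorm(1, 0, 0.1),
              dilution_factor = kit$dilution_factor,
              stringsAsFactors = FALSE
            )
          })
      }
    }
  }

  # one kitome control per kit, drawn from the contaminant profile only;
  # read yield scales with the kit's reagent load so that clean kits produce
  # shallow kitomes and high M/C ratios
  for (kit in kits) {
    sid <- sprintf("kitome_%s", kit$name)
    kdepth <- round(depth * min(1, kit$contaminant_load_ng /
                                  kitome_reference_load))
    rows[[sid]] <- sample_counts(contam, kdepth,
                                 derive_seed(seed, "kitome", kit$name))
    meta[[sid]] <- data.frame(
      sample_id = sid, species = CONTROL_SPECIES, kit = kit$name,
      replicate = 1L, is_control = TRUE,
      dna_conc = 0.1, input_mass = NA_real_, din = NA_real_,
      a260_280 = NA_real_, a260_230 = NA_real_,
      dilution_factor = kit$dilution_factor, stringsAsFactors = FALSE
    )
  }

  otu_ids <- taxonomy$otu_id
  otu <- matrix(0L, nrow = length(rows), ncol = length(otu_ids),
                dimnames = list(names(rows), otu_ids))
  for (sid in names(rows)) {
    otu[sid, names(rows[[sid]])] <- rows[[sid]]
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  kit_profiles <- data.frame(
    kit = vapply(kits, `[[`, "", "name"),
    simplicity = vapply(kits, `[[`, 1L, "simplicity"),
    cost_per_sample = vapply(kits, `[[`, 1, "cost_per_sample"),
    stringsAsFactors = FALSE
  )

  structure(
    list(otu = otu, taxonomy = taxonomy, metadata = metadata,
         kits = kit_profiles, truth = truth,
         params = list(n_replicates = n_replicates, depth = depth,
                       seed = seed)),
    class = "kitbench_dataset"
  )
}

#' @export
print.kitbench_dataset <- function(x, ...) {
  cat("Synthetic kit-benchmark dataset\n")
  cat(sprintf("  %d samples x %d OTUs (depth %d)\n",
              nrow(x$otu), ncol(x$otu), x$params$depth))
  cat(sprintf("  species: %s\n",
              paste(setdiff(unique(x$metadata$species), CONTROL_SPECIES),
                    collapse = ", ")))
  cat(sprintf("  kits: %s\n", paste(x$kits$kit, collapse = ", ")))
  cat(sprintf("  planted contaminant OTUs: %d; chloroplast OTUs: %d\n",
              length(x$truth$contaminant_otu_ids),
              length(x$truth$chloroplast_otu_ids)))
  invisible(x)
}
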