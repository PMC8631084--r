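#' Class-specific effective migration rates
#'
#' Converts per-generation replaced fractions of the recipient's females
#' (`m_f`) and males (`m_m`) into the per-generation migrant allele-frequency
#' weights felt by each chromosome class, by copy counting at a 1:1 sex
#' ratio: autosomes carry one copy from each parent sex, the X carries two
#' female-inherited copies for every male-inherited one, and mitochondria are
#' maternal only. Hence `m_A = (m_f + m_m)/2`, `m_X = (2 m_f + m_m)/3`,
#' `m_mito = m_f`. Purely male-mediated gene flow (`m_f = 0`) therefore hits
#' the X at 2/3 the autosomal rate and leaves mitochondria untouched — the
#' mechanical core of the nuclear-swamping signature.
#'
#' @param m_f,m_m Per-generation replaced fractions in `[0, 1]`.
#' @return One-row tibble with `m_autosome`, `m_x`, `m_mito`.
#' @export
effective_rates <- function(m_f, m_m) {
  if (any(c(m_f, m_m) < 0) || any(c(m_f, m_m) > 1)) {
    abort("migration rates must lie in [0, 1]")
  }
  tibble(
    m_autosome = (m_f + m_m) / 2,
    m_x = (2 * m_f + m_m) / 3,
    m_mito = m_f
  )
}

#' Demographic events
#'
#' Builders for the rows of a [demographic_model()] event table. Times are in
#' generations, increasing forward from 0 (the founder population). A split
#' replaces the parent population by two children; a pulse instantaneously
#' replaces fractions `alpha_f` / `alpha_m` of the recipient's females/males
#' with migrants; continuous migration applies per-generation fractions
#' `m_f` / `m_m` during generations `start + 1 .. end`.
#'
#' @param time,start,end Generation indices.
#' @param parent,children,donor,recipient Population labels.
#' @param alpha_f,alpha_m,m_f,m_m Sex-specific fractions in `[0, 1]`.
#' @return One-row event tibble.
#' @export
ev_split <- function(time, parent, children) {
  stopifnot(length(children) == 2L)
  tibble(type = "split", time = time, pop1 = parent,
         pop2 = children[1], pop3 = children[2],
         m_f = NA_real_, m_m = NA_real_, end = NA_real_)
}

#' @rdname ev_split
#' @export
ev_pulse <- function(time, donor, recipient, alpha_f, alpha_m) {
  tibble(type = "pulse", time = time, pop1 = donor, pop2 = recipient,
         pop3 = NA_character_, m_f = alpha_f, m_m = alpha_m, end = NA_real_)
}

#' @rdname ev_split
#' @export
ev_migration <- function(start, end, donor, recipient, m_f, m_m) {
  stopifnot(end >= start)
  tibble(type = "migration", time = start, pop1 = donor, pop2 = recipient,
         pop3 = NA_character_, m_f = m_f, m_m = m_m, end = end)
}

#' Assemble a demographic model
#'
#' A timeline of splits, pulses and continuous sex-specific migration over
#' populations of given diploid size `N` (1:1 sex ratio assumed; `N = Inf`
#' freezes a population's frequencies, the zero-drift limit). Exactly one
#' founding population must exist (never appearing as a split child), and no
#' population may be used before its creation or after its replacement by a
#' split.
#'
#' @param populations Tibble `name`, `N` listing every population on the
#'   timeline.
#' @param events Event tibble built from [ev_split()] / [ev_pulse()] /
#'   [ev_migration()] rows.
#' @param end_time Final generation (sampling time).
#' @param sample_plan Tibble `population`, `n_females`, `n_males` for the
#'   terminal sampling step.
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(populations, events, end_time, sample_plan) {
  populations <- as_tibble(populations)
  if (is.null(events) || nrow(as_tibble(events)) == 0L) {
    events <- tibble(type = character(), time = numeric(), pop1 = character(),
                     pop2 = character(), pop3 = character(), m_f = numeric(),
                     m_m = numeric(), end = numeric())
  }
  events <- as_tibble(events)
  sample_plan <- as_tibble(sample_plan)
  if (!all(c("name", "N") %in% names(populations))) abort("populations needs name, N")
  if (anyDuplicated(populations$name)) abort("duplicated population name")
  if (any(populations$N < 2)) abort("population size N must be >= 2")
  children <- unlist(events[events$type == "split", c("pop2", "pop3")])
  founders <- setdiff(populations$name, children)
  if (length(founders) != 1L) {
    abort(sprintf("model needs exactly one founding population, found %d", length(founders)))
  }
  used <- unique(stats::na.omit(unlist(events[, c("pop1", "pop2", "pop3")])))
  unknown <- setdiff(used, populations$name)
  if (length(unknown)) abort(paste0("events reference unknown population(s): ",
                                    paste(unknown, collapse = ", ")))
  rates <- events[events$type != "split", c("m_f", "m_m")]
  if (nrow(rates) && (any(rates < 0, na.rm = TRUE) || any(rates > 1, na.rm = TRUE))) {
    abort("sex-specific fractions must lie in [0, 1]")
  }
  if (any(events$time < 0) || any(events$time > end_time) ||
      any(events$end > end_time, na.rm = TRUE)) {
    abort("event times must lie in [0, end_time]")
  }
  bad_plan <- setdiff(sample_plan$population, populations$name)
  if (length(bad_plan)) abort("sample_plan references unknown populations")
  # replay the timeline once to confirm liveness of every referenced population
  alive <- founders
  ord <- order(events$time, match(events$type, c("split", "pulse", "migration")))
  for (k in ord) {
    e <- events[k, ]
    if (e$type == "split") {
      if (!e$pop1 %in% alive) abort(sprintf("split parent %s not alive at t=%g", e$pop1, e$time))
      alive <- c(setdiff(alive, e$pop1), e$pop2, e$pop3)
    } else {
      if (!all(c(e$pop1, e$pop2) %in% alive)) {
        abort(sprintf("%s at t=%g references a population not alive", e$type, e$time))
      }
    }
  }
  missing_sampled <- setdiff(sample_plan$population, alive)
  if (length(missing_sampled)) {
    abort(paste0("sampled population(s) not alive at end_time: ",
                 paste(missing_sampled, collapse = ", ")))
  }
  structure(list(populations = populations, events = events,
                 end_time = end_time, sample_plan = sample_plan, founder = founders),
            class = "demographic_model")
}

#' Locus panel layout
#'
#' Describes the simulated SNV panel: counts per chromosome class, the
#' chromosome layout assigning positions (fixed spacing, so a 5-Mb jackknife
#' partition has a predictable block count), and the ancestral-frequency
#' sampler. The default panel — 10,000 autosomal loci on 20 chromosomes and
#' 4,000 X loci at 25-kb spacing — yields 60 autosomal and 20 X blocks of
#' 5 Mb. Ancestral frequencies default to a symmetric Beta(0.8, 0.8)
#' truncated to the range 0.05-0.95, a polymorphism-rich spectrum resembling a
#' complete-case SNV panel.
#'
#' @param n_autosomal,n_x,n_mito Locus counts per class.
#' @param n_auto_chrom Number of autosomes carrying the autosomal loci.
#' @param spacing Distance between adjacent loci in bp.
#' @param sampler `"beta"` or `"uniform"` ancestral frequency sampler.
#' @param beta_shape Shape of the symmetric Beta sampler.
#' @param freq_range Truncation range of ancestral frequencies.
#' @return A `locus_plan` object (site tibble blueprint + sampler spec).
#' @export
locus_plan <- function(n_autosomal = 10000, n_x = 4000, n_mito = 1,
                       n_auto_chrom = 20, spacing = 25000,
                       sampler = c("beta", "uniform"),
                       beta_shape = 0.8, freq_range = c(0.05, 0.95)) {
  sampler <- match.arg(sampler)
  per_chrom <- ceiling(n_autosomal / n_auto_chrom)
  chrom <- rep(paste0("chr", seq_len(n_auto_chrom)), each = per_chrom)[seq_len(n_autosomal)]
  pos_a <- (sequence(rle(chrom)$lengths) - 1) * spacing + 1
  sites <- tibble(
    chrom = c(chrom,
              rep("chrX", n_x),
              rep("chrM", n_mito)),
    pos = as.integer(c(pos_a,
                       (seq_len(n_x) - 1) * spacing + 1,
                       seq_len(n_mito))),
    ref = "A", alt = "C",
    chrom_class = c(rep("autosome", n_autosomal), rep("X", n_x), rep("mito", n_mito))
  )
  structure(list(sites = sites, sampler = sampler, beta_shape = beta_shape,
                 freq_range = freq_range,
                 n = c(autosome = n_autosomal, X = n_x, mito = n_mito)),
            class = "locus_plan")
}

draw_ancestral_freq <- function(plan, n) {
  p <- if (plan$sampler == "beta") {
    stats::rbeta(n, plan$beta_shape, plan$beta_shape)
  } else {
    stats::runif(n)
  }
  pmin(pmax(p, plan$freq_range[1]), plan$freq_range[2])
}

# per-class haploid copy numbers for a diploid population of size N (1:1 sexes)
class_copies <- function(N) {
  if (!is.finite(N)) return(c(autosome = Inf, X = Inf, mito = Inf))
  c(autosome = 2 * N, X = floor(3 * N / 2), mito = floor(N / 2))
}

#' Forward Wright-Fisher simulation of a demographic model
#'
#' Frequency-level simulation: each locus carries an ancestral frequency;
#' every generation each living population's frequency vector is binomially
#' resampled with the class-specific copy number (2N autosomal, floor(3N/2)
#' X-linked, floor(N/2) mitochondrial), after applying any active migration
#' as the deterministic update `p <- (1 - w) p + w p_donor` with the
#' class-specific weight `w` from [effective_rates()]. Sampling draws
#' genotypes binomially at the final frequencies with correct per-sample
#' ploidy. Alongside the genotypes a truth record tracks, per population and
#' chromosome class, the realised ancestry decomposition over source
#' populations (each population starts as 100% itself at creation; migration
#' mixes donor ancestry in with the same weights).
#'
#' @param model A [demographic_model()].
#' @param plan A [locus_plan()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `genotypes` (a [geno_matrix()]), and `truth`: final
#'   per-population frequencies (`freq`), the ancestry table (`ancestry`:
#'   population, class, source, fraction), founder frequencies, and the
#'   model/plan/seed.
#' @export
simulate_genotypes <- function(model, plan, seed = 1) {
  set.seed(seed)
  classes <- CHROM_CLASSES
  nl <- plan$n
  founder <- model$founder
  p0 <- lapply(classes, function(cl) draw_ancestral_freq(plan, nl[[cl]]))
  names(p0) <- classes
  Ns <- stats::setNames(model$populations$N, model$populations$name)

  freq <- list()
  freq[[founder]] <- p0
  # ancestry[[pop]][[class]]: named vector of proportions over source labels
  ancestry <- list()
  ancestry[[founder]] <- stats::setNames(
    rep(list(stats::setNames(1, founder)), 3), classes)

  ev <- model$events
  mix_anc <- function(a, b, w) {
    src <- union(names(a), names(b))
    av <- stats::setNames(numeric(length(src)), src)
    av[names(a)] <- av[names(a)] + (1 - w) * a
    av[names(b)] <- av[names(b)] + w * b
    av
  }
  apply_flow <- function(donor, recipient, m_f, m_m) {
    w <- effective_rates(m_f, m_m)
    wts <- c(autosome = w$m_autosome, X = w$m_x, mito = w$m_mito)
    for (cl in classes) {
      if (wts[[cl]] == 0 || nl[[cl]] == 0) next
      freq[[recipient]][[cl]] <<- (1 - wts[[cl]]) * freq[[recipient]][[cl]] +
        wts[[cl]] * freq[[donor]][[cl]]
      ancestry[[recipient]][[cl]] <<- mix_anc(ancestry[[recipient]][[cl]],
                                              ancestry[[donor]][[cl]], wts[[cl]])
    }
  }
  do_point_events <- function(t) {
    rows <- which(ev$time == t & ev$type != "migration")
    for (k in rows) {
      e <- ev[k, ]
      if (e$type == "split") {
        for (child in c(e$pop2, e$pop3)) {
          freq[[child]] <<- freq[[e$pop1]]
          ancestry[[child]] <<- stats::setNames(
            rep(list(stats::setNames(1, child)), 3), classes)
        }
        freq[[e$pop1]] <<- NULL
        ancestry[[e$pop1]] <<- NULL
      } else {
        apply_flow(e$pop1, e$pop2, e$m_f, e$m_m)
      }
    }
  }
  do_point_events(0)
  if (model$end_time >= 1) for (t in seq_len(model$end_time)) {
    do_point_events(t)
    mig <- which(ev$type == "migration" & ev$time < t & t <= ev$end)
    for (k in mig) apply_flow(ev$pop1[k], ev$pop2[k], ev$m_f[k], ev$m_m[k])
    for (pop in names(freq)) {
      cc <- class_copies(Ns[[pop]])
      for (cl in classes) {
        n_cop <- cc[[cl]]
        if (!is.finite(n_cop) || nl[[cl]] == 0) next
        freq[[pop]][[cl]] <- stats::rbinom(nl[[cl]], n_cop, freq[[pop]][[cl]]) / n_cop
      }
    }
  }

  # terminal sampling
  sp <- model$sample_plan
  samples <- purrr::pmap(sp, function(population, n_females, n_males) {
    tibble(
      sample_id = c(if (n_females > 0) paste0(population, "_F", seq_len(n_females)),
                    if (n_males > 0) paste0(population, "_M", seq_len(n_males))),
      population = population,
      sex = c(rep("female", n_females), rep("male", n_males))
    )
  }) |> dplyr::bind_rows()
  sites <- plan$sites
  ploidy <- ploidy_matrix(sites$chrom_class, samples$sex)
  dosage <- matrix(NA_integer_, nrow(sites), nrow(samples))
  class_rows <- lapply(classes, function(cl) which(sites$chrom_class == cl))
  names(class_rows) <- classes
  for (j in seq_len(nrow(samples))) {
    pop <- samples$population[j]
    for (cl in classes) {
      rows <- class_rows[[cl]]
      if (!length(rows)) next
      dosage[rows, j] <- stats::rbinom(length(rows), ploidy[rows, j], freq[[pop]][[cl]])
    }
  }
  gm <- geno_matrix(sites, samples, dosage, ploidy)
  anc_tbl <- purrr::imap(ancestry, function(by_class, pop) {
    purrr::imap(by_class, function(v, cl) {
      tibble(population = pop, class = cl, source = names(v), fraction = unname(v))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  list(
    genotypes = gm,
    truth = list(freq = freq, ancestry = anc_tbl, founder_freq = p0,
                 model = model, plan = plan, seed = seed)
  )
}

#' The nuclear-swamping scenario
#'
#' Builds and simulates the canonical four-population test layout: outgroup A
#' splits first; the remaining lineage splits into the donor-side lineage
#' (which itself splits into sampled D and its unsampled sister Dp) and the
#' sister pair B, C. After the B-C split, strong continuous purely
#' male-mediated migration flows from Dp into C (`m_f = 0`,
#' `m_m = strength`) for `duration` generations until sampling. Autosomes in
#' C are swamped by donor ancestry faster than the X (per-generation pressure
#' ratio 3:2), and C's mitochondrial lineage stays entirely original —
#' f4(A, B; C, D) is therefore negative on both classes but more strongly
#' negative on the X.
#'
#' @param strength Per-generation replaced fraction of C's males, in (0, 1).
#' @param duration Number of migrating generations (>= 1).
#' @param seed Integer seed.
#' @param N Diploid population size (all populations).
#' @param n_females,n_males Samples drawn per population.
#' @param plan A [locus_plan()].
#' @param sample_donor_sister Also sample the donor population Dp. The f4
#'   contrast needs only A-D; admixture-graph fitting needs the donor-side
#'   split observed on both sides to pin the mixing proportion (with leaves
#'   A-D only, alpha trades off against the unobserved donor drift along a
#'   flat ridge), so graph analyses should set this to `TRUE`.
#' @return As [simulate_genotypes()], plus the `model` used.
#' @export
nuclear_swamping_scenario <- function(strength = 0.05, duration = 30, seed = 1,
                                      N = 500, n_females = 5, n_males = 5,
                                      plan = locus_plan(),
                                      sample_donor_sister = FALSE) {
  if (strength <= 0 || strength >= 1) abort("strength must lie in (0, 1)")
  if (duration < 1) abort("duration must be >= 1")
  t_bc <- 130
  end_time <- t_bc + duration
  pops <- tibble(
    name = c("ROOT", "A", "R1", "D0", "BC", "D", "Dp", "B", "C"),
    N = N
  )
  events <- dplyr::bind_rows(
    ev_split(0, "ROOT", c("A", "R1")),
    ev_split(10, "R1", c("D0", "BC")),
    ev_split(30, "D0", c("D", "Dp")),
    ev_split(t_bc, "BC", c("B", "C")),
    ev_migration(t_bc, end_time, "Dp", "C", m_f = 0, m_m = strength)
  )
  plan_pops <- c("A", "B", "C", "D", if (sample_donor_sister) "Dp")
  model <- demographic_model(
    pops, events, end_time,
    tibble(population = plan_pops, n_females = n_females, n_males = n_males)
  )
  sim <- simulate_genotypes(model, plan, seed)
  c(sim, list(model = model))
}

#' A single sex-unbiased admixture pulse scenario
#'
#' Five sampled populations in the identifiable graph shape: outgroup A, the
#' donor-side sister pair (D, Dp), and the recipient-side pair (B, C). A
#' single pulse replaces fraction `alpha` of C (both sexes equally) from Dp,
#' followed by post-admixture drift until sampling. The realised admixture
#' fraction equals `alpha` on every chromosome class, making this the
#' reference scenario for admixture-proportion recovery.
#'
#' @param alpha Pulse fraction in (0, 1), both sexes.
#' @param seed Integer seed.
#' @param N Diploid population size.
#' @param n_females,n_males Samples per population.
#' @param plan A [locus_plan()].
#' @return As [simulate_genotypes()], plus the `model`.
#' @export
admixture_pulse_scenario <- function(alpha = 0.3, seed = 1, N = 500,
                                     n_females = 5, n_males = 5,
                                     plan = locus_plan()) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  pops <- tibble(
    name = c("ROOT", "A", "R1", "D0", "BC", "D", "Dp", "B", "C"),
    N = N
  )
  events <- dplyr::bind_rows(
    ev_split(0, "ROOT", c("A", "R1")),
    ev_split(10, "R1", c("D0", "BC")),
    ev_split(90, "D0", c("D", "Dp")),
    ev_split(100, "BC", c("B", "C")),
    ev_pulse(130, "Dp", "C", alpha_f = alpha, alpha_m = alpha)
  )
  model <- demographic_model(
    pops, events, end_time = 160,
    tibble(population = c("A", "B", "C", "D", "Dp"),
           n_females = n_females, n_males = n_males)
  )
  sim <- simulate_genotypes(model, plan, seed)
  c(sim, list(model = model))
}

#' Realised donor ancestry per chromosome class
#'
#' Convenience accessor on a simulation truth record: total ancestry fraction
#' of `population` attributable to sources other than itself (i.e., received
#' through pulses or migration since its creation).
#'
#' @param truth The `truth` element of a [simulate_genotypes()] result.
#' @param population Recipient population label.
#' @return Tibble `class`, `donor_fraction`.
#' @export
donor_ancestry <- function(truth, population) {
  truth$ancestry |>
    dplyr::filter(.data$population == !!population) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(donor_fraction = sum(.data$fraction[.data$source != !!population]),
                     .groups = "drop")
}
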