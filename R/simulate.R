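#' Configuration for the paired methylome/transcriptome simulator
#'
#' Builds a validated configuration for [simulate_dataset()] and the
#' individual simulation stages. Defaults emulate the statistical
#' structure of paired scBS-seq/scRNA-seq profiling of germinal-vesicle
#' oocytes from young and aged females: 30/32 cells with methylomes and
#' 42/45 with transcriptomes, per-cell CpG coverage between 3.4% and
#' 29.9% of sites, a bimodal domain landscape with hypermethylated
#' (75-100%) and hypomethylated (0-25%) domains of median size 20.9 and
#' 24.9 kbp, planted age-associated DMRs of which 88% lose methylation
#' in the aged group, negative-binomial expression with age-dependent
#' mean and dispersion changes, an SN-signature of at least two-fold
#' overexpression, and genes whose gene-body methylation tracks their
#' expression cell by cell.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_young_meth,n_aged_meth Cells with methylomes per group.
#' @param n_young_rna,n_aged_rna Cells with transcriptomes per group
#'   (methylome cells are the leading subset of each).
#' @param genome_length Autosomal genome length simulated (bp).
#' @param cpg_spacing_mean Mean CpG spacing (bp).
#' @param coverage_range Per-cell covered fraction of CpG sites,
#'   drawn uniformly from this interval.
#' @param n_true_dmrs Number of planted DMR domains.
#' @param dmr_delta Methylation-proportion difference of planted DMRs.
#' @param dmr_hypo_fraction Probability a planted DMR loses methylation
#'   in the aged group.
#' @param hyper_median_kb,hypo_median_kb,inter_median_kb Median domain
#'   sizes (kbp) of the log-normal size distributions.
#' @param domain_sdlog Log-scale SD of domain sizes.
#' @param cell_rate_noise_sd SD of the per-cell global shift around
#'   domain rates (methylation fraction).
#' @param aged_global_shift Additive shift of aged-cell methylation
#'   rates (fraction; default -0.01, a one-point global reduction).
#' @param noncpg_base Baseline non-CpG methylation rate.
#' @param noncpg_cpg_slope Dependence of the non-CpG rate on the local
#'   CpG rate.
#' @param noncpg_aged_shift Additive non-CpG shift in aged cells.
#' @param reads_per_site Calls simulated per covered site (1 mirrors
#'   scBS-seq; larger values give pseudobulk-like fixtures).
#' @param n_genes,n_de,n_dv,n_signature,n_coupled,n_maternal Gene set
#'   sizes (disjoint; their sum must not exceed `n_genes`).
#' @param de_lfc Log2 fold change magnitude of planted DE genes.
#' @param de_down_fraction Fraction of DE genes losing expression in
#'   aged cells.
#' @param nb_dispersion_inflation Dispersion multiplier for DV genes in
#'   the more-variable group.
#' @param dv_up_fraction Fraction of DV genes more variable in aged.
#' @param sn_fold Fold change of signature genes in SN cells (>= 2).
#' @param n_sn_young,n_sn_aged SN cells per age group.
#' @param n_young_like Aged cells with a young-like transcriptome (DE
#'   and coupled effects absent); includes every aged SN cell.
#' @param maternal_lfc_per_cluster Log2 change of maternal-effect genes
#'   per cluster step (clusters ordered 1-4).
#' @param diversity_deficit Expected number of detected genes lost per
#'   aged cell (extra dropout of background genes).
#' @param nb_size Baseline negative-binomial size (1/dispersion).
#' @param mu_meanlog,mu_sdlog Log-normal parameters of gene mean
#'   expression.
#' @param sf_sdlog Log-scale SD of true per-cell size factors.
#' @param coupling_base,coupling_slope Gene-body methylation of coupled
#'   genes: `base + slope * z` (z = standardised log-normalised
#'   expression), clipped to `[0.02, 0.98]`.
#' @param coupled_lfc Log2 fold change magnitude of coupled genes in
#'   aged cells (random sign per gene).
#' @param n_gene_bodies Genes given gene-body intervals (first the
#'   coupled genes, then uncoupled fillers), placed in hyper domains.
#' @param gene_body_kb Gene-body length (kbp).
#' @param n_gdmr_maternal,n_gdmr_paternal,n_secondary_dmr Imprinted
#'   control regions planted with age-invariant methylation.
#' @param gdmr_kb gDMR length (kbp).
#' @param gdmr_maternal_rate,gdmr_paternal_rate Their methylation rates.
#' @param x_length Simulated X-chromosome length (bp).
#' @param n_x_cgi,x_cgi_kb,x_cgi_rate X-chromosome CpG islands (the
#'   contamination control; low methylation in oocytes).
#' @param x_background_rate Background methylation rate on the X.
#' @return A validated list of class `oomt_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_young_meth = 30, n_aged_meth = 32,
                       n_young_rna = 42, n_aged_rna = 45,
                       genome_length = 8e6, cpg_spacing_mean = 100,
                       coverage_range = c(0.034, 0.299),
                       n_true_dmrs = 50, dmr_delta = 0.20,
                       dmr_hypo_fraction = 0.88,
                       hyper_median_kb = 20.9, hypo_median_kb = 24.9,
                       inter_median_kb = 10, domain_sdlog = 0.5,
                       cell_rate_noise_sd = 0.02,
                       aged_global_shift = -0.01,
                       noncpg_base = 0.02, noncpg_cpg_slope = 0.08,
                       noncpg_aged_shift = 0.005,
                       reads_per_site = 1,
                       n_genes = 12000, n_de = 560, n_dv = 1500,
                       n_signature = 100, n_coupled = 20, n_maternal = 60,
                       de_lfc = 1, de_down_fraction = 0.536,
                       nb_dispersion_inflation = 3, dv_up_fraction = 0.97,
                       sn_fold = 2, n_sn_young = 12, n_sn_aged = 8,
                       n_young_like = 16,
                       maternal_lfc_per_cluster = -0.5,
                       diversity_deficit = 1147,
                       nb_size = 5, mu_meanlog = 3, mu_sdlog = 1.5,
                       sf_sdlog = 0.2,
                       coupling_base = 0.35, coupling_slope = 0.15,
                       coupled_lfc = 0.8,
                       n_gene_bodies = 40, gene_body_kb = 10,
                       n_gdmr_maternal = 19, n_gdmr_paternal = 3,
                       n_secondary_dmr = 2, gdmr_kb = 2,
                       gdmr_maternal_rate = 0.95, gdmr_paternal_rate = 0.03,
                       x_length = 1e6, n_x_cgi = 20, x_cgi_kb = 1,
                       x_cgi_rate = 0.03, x_background_rate = 0.3) {
  cfg <- as.list(environment())
  counts <- cfg[c("n_young_meth", "n_aged_meth", "n_young_rna",
                  "n_aged_rna", "n_true_dmrs", "n_genes", "n_de", "n_dv",
                  "n_signature", "n_coupled", "n_maternal")]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (cfg$n_young_meth > cfg$n_young_rna || cfg$n_aged_meth > cfg$n_aged_rna)
    stop("methylome cells are a subset of transcriptome cells")
  if (length(coverage_range) != 2L || any(coverage_range <= 0) ||
        any(coverage_range > 1) || coverage_range[1] > coverage_range[2])
    stop("coverage_range must be an increasing pair within (0, 1]")
  if (dmr_delta <= 0 || dmr_delta >= 1)
    stop("dmr_delta must lie in (0, 1)")
  if (dmr_hypo_fraction < 0 || dmr_hypo_fraction > 1)
    stop("dmr_hypo_fraction must lie in [0, 1]")
  if (sn_fold < 2) stop("sn_fold must be >= 2")
  if (n_de + n_dv + n_signature + n_coupled + n_maternal > n_genes)
    stop("planted gene sets exceed n_genes")
  if (n_coupled > n_gene_bodies)
    stop("n_gene_bodies must cover all coupled genes")
  if (n_sn_young > n_young_rna || n_sn_aged > n_aged_rna)
    stop("SN cell counts exceed group sizes")
  if (n_young_like > n_aged_rna || n_young_like < n_sn_aged)
    stop("n_young_like must cover all aged SN cells and fit the aged group")
  if (reads_per_site < 1) stop("reads_per_site must be >= 1")
  structure(cfg, class = "oomt_sim_config")
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Simulate the bimodal methylation domain landscape
#'
#' Tiles the autosomal genome with an alternating sequence of
#' hypermethylated, intermediate and hypomethylated domains (cycle:
#' hyper, inter, hypo, inter, hypo, inter — two hypo domains per hyper
#' domain, which reproduces a global methylation level near the
#' observed 30-40% given the class rate ranges). Domain sizes are drawn
#' log-normal with class-specific medians; each domain receives a true
#' methylation rate uniform within its class band: hyper in
#' `[0.75, 1]`, hypo in `[0, 0.25]`, intermediate in `(0.25, 0.75)`.
#'
#' @param config A [sim_config()].
#' @return A list: `domains` (a domain set on `chr1`) and `rates`
#'   (per-domain true methylation rate, young landscape).
#' @export
simulate_domain_landscape <- function(config) {
  max_median <- max(config$hyper_median_kb, config$hypo_median_kb) * 1000
  if (config$genome_length < 10 * max_median)
    stop("genome_length must be at least 10x the largest median domain ",
         "size (", 10 * max_median, " bp)")
  cycle <- c("hyper", "inter", "hypo", "inter", "hypo", "inter")
  medians <- c(hyper = config$hyper_median_kb,
               hypo = config$hypo_median_kb,
               inter = config$inter_median_kb) * 1000
  n_guess <- ceiling(config$genome_length / (sum(medians[cycle]) / 6) * 1.5) + 6
  classes <- rep(cycle, length.out = n_guess)
  sizes <- round(stats::rlnorm(n_guess, meanlog = log(medians[classes]),
                               sdlog = config$domain_sdlog))
  sizes <- pmax(sizes, 200L)
  ends <- cumsum(sizes)
  keep <- which(ends - sizes < config$genome_length)
  classes <- classes[keep]; sizes <- sizes[keep]; ends <- ends[keep]
  starts <- ends - sizes
  starts[1L] <- 0L
  ends[length(ends)] <- config$genome_length  # tile flush to the end
  rates <- numeric(length(classes))
  rates[classes == "hyper"] <- stats::runif(sum(classes == "hyper"), 0.75, 1)
  rates[classes == "hypo"]  <- stats::runif(sum(classes == "hypo"), 0, 0.25)
  rates[classes == "inter"] <- stats::runif(sum(classes == "inter"), 0.25, 0.75)
  domains <- domain_set(chrom = "chr1", start = starts, end = ends,
                        name = sprintf("%s_%04d", classes,
                                       seq_along(classes)),
                        class = classes)
  list(domains = domains, rates = rates)
}

#' Plant true age-associated DMRs on a landscape
#'
#' Copies the young landscape and shifts the aged rate of
#' `n_true_dmrs` randomly chosen domains by `dmr_delta`, downwards with
#' probability `dmr_hypo_fraction` (hypo in aged) and upwards
#' otherwise, clipping to `[0, 1]` and recording the effective
#' (post-clipping) delta. All remaining domains are identical between
#' groups.
#'
#' @param landscape Output of [simulate_domain_landscape()].
#' @param config A [sim_config()].
#' @param exclude Optional domain names never chosen as DMRs.
#' @return A list: `rates_aged` (per-domain aged rates) and `truth`
#'   (`data.frame` with `name`, `direction`, `delta_effective`).
#' @export
place_true_dmrs <- function(landscape, config, exclude = character()) {
  domains <- landscape$domains
  eligible <- setdiff(domains$name, exclude)
  if (config$n_true_dmrs > length(eligible))
    stop("n_true_dmrs exceeds the number of eligible domains")
  rates_aged <- landscape$rates
  if (config$n_true_dmrs == 0L)
    return(list(rates_aged = rates_aged,
                truth = data.frame(name = character(),
                                   direction = character(),
                                   delta_effective = numeric(),
                                   stringsAsFactors = FALSE)))
  chosen <- sample(eligible, config$n_true_dmrs)
  idx <- match(chosen, domains$name)
  hypo <- stats::runif(length(idx)) < config$dmr_hypo_fraction
  target <- landscape$rates[idx] + ifelse(hypo, -1, 1) * config$dmr_delta
  rates_aged[idx] <- clip01(target)
  truth <- data.frame(
    name = chosen,
    direction = ifelse(hypo, "hypo_in_aged", "hyper_in_aged"),
    delta_effective = abs(rates_aged[idx] - landscape$rates[idx]),
    stringsAsFactors = FALSE)
  list(rates_aged = rates_aged, truth = truth)
}

#' Simulate CpG (or non-CpG) site positions
#'
#' Places sites along a chromosome with approximately exponential
#' spacing of the requested mean (minimum 2 bp between sites).
#'
#' @param length_bp Chromosome length.
#' @param spacing_mean Mean spacing (bp).
#' @param chrom Chromosome name.
#' @param context Sequence context of the sites.
#' @return A `data.frame` with `chrom`, `pos` (1-based), `context`.
#' @export
simulate_cpg_sites <- function(length_bp, spacing_mean, chrom = "chr1",
                               context = "CpG") {
  n_guess <- ceiling(length_bp / spacing_mean * 1.3) + 10
  gaps <- pmax(2, round(stats::rexp(n_guess, 1 / spacing_mean)))
  pos <- cumsum(gaps)
  pos <- pos[pos <= length_bp]
  data.frame(chrom = chrom, pos = as.integer(pos), context = context,
             stringsAsFactors = FALSE)
}

#' Simulate one cell's methylation calls
#'
#' Each site is covered independently with probability
#' `coverage_fraction`; a covered site receives `reads_per_site`
#' binomial calls at the site's true methylation rate. With the default
#' single read per site, counts are binary — (1,0) or (0,1) — which is
#' the scBS-seq regime.
#'
#' @param sites Site table from [simulate_cpg_sites()] (possibly several
#'   chromosomes/contexts bound together).
#' @param rates Per-site true methylation rates, aligned with `sites`.
#' @param coverage_fraction Fraction of sites covered, in `(0, 1]`.
#' @param seed Optional integer seed (the call is then self-contained
#'   and reproducible; otherwise it consumes the ambient RNG stream).
#' @param reads_per_site Calls per covered site (default 1).
#' @return A CpG call table of the covered sites.
#' @export
simulate_cell_methylome <- function(sites, rates, coverage_fraction,
                                    seed = NULL, reads_per_site = 1) {
  stopifnot(length(rates) == nrow(sites),
            coverage_fraction > 0, coverage_fraction <= 1)
  run <- function() {
    covered <- stats::runif(nrow(sites)) < coverage_fraction
    n <- sum(covered)
    meth <- stats::rbinom(n, reads_per_site, clip01(rates[covered]))
    cpg_calls(chrom = sites$chrom[covered], pos = sites$pos[covered],
              context = sites$context[covered], meth = meth,
              unmeth = reads_per_site - meth)
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Simulate the expression matrix with planted ground truth
#'
#' Draws a genes x cells negative-binomial count matrix with per-cell
#' size factors and planted structure: DE genes shifted in aged cells
#' (except young-like cells), DV genes with inflated dispersion in the
#' more-variable group, SN-signature genes overexpressed `sn_fold`-fold
#' in SN cells, maternal-effect genes trending across the four ordered
#' cell clusters, coupled genes shifted like DE genes, and extra
#' dropout of background genes in aged cells to reduce their transcript
#' diversity.
#'
#' @param config A [sim_config()].
#' @return A list: `counts` (genes x cells), `annotation` (`data.frame`
#'   with `cell_id`, `age_group`, `chromatin_state`, `young_like`,
#'   `cluster_id`, `has_methylome`), `truth` (gene sets with effect
#'   sizes and per-cell true labels), `size_factors` (true per-cell
#'   factors).
#' @export
simulate_expression <- function(config) {
  cfg <- config
  genes <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  cells <- c(sprintf("young_%02d", seq_len(cfg$n_young_rna)),
             sprintf("aged_%02d", seq_len(cfg$n_aged_rna)))
  age <- rep(c("young", "aged"), c(cfg$n_young_rna, cfg$n_aged_rna))

  # disjoint planted gene sets
  pool <- sample(genes)
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  de_genes <- take(cfg$n_de)
  dv_genes <- take(cfg$n_dv)
  sig_genes <- take(cfg$n_signature)
  coupled_genes <- take(cfg$n_coupled)
  maternal_genes <- take(cfg$n_maternal)
  background <- pool

  sn_cells <- c(sample(cells[age == "young"], cfg$n_sn_young),
                sample(cells[age == "aged"], cfg$n_sn_aged))
  state <- ifelse(cells %in% sn_cells, "SN", "NSN")
  aged_cells <- cells[age == "aged"]
  aged_sn <- intersect(sn_cells, aged_cells)
  young_like <- c(aged_sn,
                  sample(setdiff(aged_cells, aged_sn),
                         cfg$n_young_like - length(aged_sn)))
  is_yl <- cells %in% young_like
  cluster <- ifelse(age == "young" & state == "SN", 1L,
             ifelse(age == "young", 2L,
             ifelse(is_yl, 3L, 4L)))

  mu <- stats::rlnorm(cfg$n_genes, cfg$mu_meanlog, cfg$mu_sdlog)
  names(mu) <- genes
  sf <- stats::rlnorm(length(cells), 0, cfg$sf_sdlog)
  names(sf) <- cells

  de_sign <- ifelse(stats::runif(cfg$n_de) < cfg$de_down_fraction, -1, 1)
  de_lfc <- de_sign * cfg$de_lfc
  names(de_lfc) <- de_genes
  coupled_lfc <- sample(c(-1, 1), cfg$n_coupled, replace = TRUE) *
    cfg$coupled_lfc
  names(coupled_lfc) <- coupled_genes
  dv_up <- stats::runif(cfg$n_dv) < cfg$dv_up_fraction
  names(dv_up) <- dv_genes

  # per-gene, per-cell mean and size
  mu_mat <- matrix(mu, cfg$n_genes, length(cells),
                   dimnames = list(genes, cells))
  affected <- age == "aged" & !is_yl
  if (cfg$n_de > 0)
    mu_mat[de_genes, affected] <- mu_mat[de_genes, affected] *
      2^de_lfc[de_genes]
  if (cfg$n_coupled > 0)
    mu_mat[coupled_genes, affected] <- mu_mat[coupled_genes, affected] *
      2^coupled_lfc[coupled_genes]
  if (cfg$n_signature > 0)
    mu_mat[sig_genes, state == "SN"] <-
      mu_mat[sig_genes, state == "SN"] * cfg$sn_fold
  if (cfg$n_maternal > 0)
    mu_mat[maternal_genes, ] <- mu_mat[maternal_genes, ] *
      2^(cfg$maternal_lfc_per_cluster *
           rep(cluster - 1L, each = cfg$n_maternal))
  mu_mat <- sweep(mu_mat, 2, sf, "*")

  size_mat <- matrix(cfg$nb_size, cfg$n_genes, length(cells),
                     dimnames = list(genes, cells))
  if (cfg$n_dv > 0) {
    up <- dv_genes[dv_up]; down <- dv_genes[!dv_up]
    size_mat[up, age == "aged"] <-
      cfg$nb_size / cfg$nb_dispersion_inflation
    size_mat[down, age == "young"] <-
      cfg$nb_size / cfg$nb_dispersion_inflation
  }

  counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                  size = size_mat),
                   cfg$n_genes, length(cells),
                   dimnames = list(genes, cells))

  # reduced transcript diversity in aged cells: extra dropout of
  # detected background genes
  if (cfg$diversity_deficit > 0 && length(background) > 0) {
    for (j in which(age == "aged")) {
      detected <- background[counts[background, j] > 0]
      k <- min(stats::rpois(1, cfg$diversity_deficit), length(detected))
      if (k > 0) counts[sample(detected, k), j] <- 0L
    }
  }
  storage.mode(counts) <- "integer"

  annotation <- data.frame(
    cell_id = cells, age_group = age, chromatin_state = state,
    young_like = is_yl, cluster_id = cluster,
    has_methylome = c(seq_len(cfg$n_young_rna) <= cfg$n_young_meth,
                      seq_len(cfg$n_aged_rna) <= cfg$n_aged_meth),
    stringsAsFactors = FALSE)

  truth <- list(
    de_genes = data.frame(gene = de_genes, lfc = unname(de_lfc),
                          stringsAsFactors = FALSE),
    dv_genes = data.frame(gene = dv_genes,
                          direction = ifelse(dv_up, "up_in_aged",
                                             "down_in_aged"),
                          stringsAsFactors = FALSE),
    signature_genes = sig_genes,
    coupled_genes = data.frame(gene = coupled_genes,
                               lfc = unname(coupled_lfc),
                               slope = rep(cfg$coupling_slope,
                                           length(coupled_genes)),
                               stringsAsFactors = FALSE),
    maternal_genes = maternal_genes,
    cell_state = stats::setNames(state, cells),
    cell_age = stats::setNames(age, cells),
    young_like = stats::setNames(is_yl, cells))

  list(counts = counts, annotation = annotation, truth = truth,
       size_factors = sf)
}

#' Simulate a complete paired methylome/transcriptome dataset
#'
#' Runs every simulation stage under a single seeded RNG stream:
#' domain landscape, planted DMRs, gDMR and X-CGI control regions, gene
#' bodies (placed inside hyper domains that are not DMRs), the
#' expression matrix, per-cell coupled gene-body methylation rates
#' derived from realised expression, and one methylome per methylome
#' cell (CpG plus non-CpG calls; the non-CpG rate follows the local
#' CpG rate). Identical configurations produce identical datasets.
#'
#' @param config A [sim_config()].
#' @return A list with components `domains`, `rates_young`,
#'   `rates_aged`, `gdmrs`, `x_cgi`, `gene_bodies`, `meth_cells`
#'   (named list of call tables), `meth_annotation`, `counts`,
#'   `annotation`, `size_factors` and `truth` (all planted structure:
#'   DMRs, gene sets, per-cell states).
#' @export
simulate_dataset <- function(config) {
  cfg <- config
  set.seed(cfg$seed)

  landscape <- simulate_domain_landscape(cfg)
  dmr <- place_true_dmrs(landscape, cfg)
  domains <- landscape$domains

  expr <- simulate_expression(cfg)
  annotation <- expr$annotation
  meth_cells_ann <- annotation[annotation$has_methylome, ]

  # control regions: gDMRs inside non-DMR domains
  non_dmr <- setdiff(domains$name, dmr$truth$name)
  n_ctrl <- cfg$n_gdmr_maternal + cfg$n_gdmr_paternal + cfg$n_secondary_dmr
  gdmrs <- NULL
  if (n_ctrl > 0) {
    host <- sample(non_dmr, n_ctrl)
    hi <- match(host, domains$name)
    width <- pmin(cfg$gdmr_kb * 1000, domains$end[hi] - domains$start[hi])
    mid <- (domains$start[hi] + domains$end[hi]) %/% 2L
    cls <- rep(c("gdmr_maternal", "gdmr_paternal", "secondary_dmr"),
               c(cfg$n_gdmr_maternal, cfg$n_gdmr_paternal,
                 cfg$n_secondary_dmr))
    gdmrs <- domain_set(chrom = "chr1",
                        start = mid - width %/% 2L,
                        end = mid - width %/% 2L + width,
                        name = sprintf("%s_%02d", cls, stats::ave(
                          seq_len(n_ctrl), cls, FUN = seq_along)),
                        class = cls)
    gdmrs$rate <- ifelse(cls == "gdmr_maternal",
                         cfg$gdmr_maternal_rate, cfg$gdmr_paternal_rate)
  }

  # gene bodies inside hyper domains that are neither DMRs nor gDMR hosts
  hyper_free <- domains$name[domains$class == "hyper" &
                               !(domains$name %in% dmr$truth$name)]
  if (!is.null(gdmrs)) {
    host_of <- domains$name[findInterval(gdmrs$start,
                                         domains$start)]
    hyper_free <- setdiff(hyper_free, host_of)
  }
  if (length(hyper_free) < cfg$n_gene_bodies)
    stop("not enough DMR-free hyper domains to host ", cfg$n_gene_bodies,
         " gene bodies; enlarge the genome or reduce n_gene_bodies")
  gene_bodies <- NULL
  if (cfg$n_gene_bodies > 0) {
    body_hosts <- sample(hyper_free, cfg$n_gene_bodies)
    bi <- match(body_hosts, domains$name)
    bw <- pmin(cfg$gene_body_kb * 1000, domains$end[bi] - domains$start[bi])
    bmid <- (domains$start[bi] + domains$end[bi]) %/% 2L
    body_genes <- unique(c(expr$truth$coupled_genes$gene,
                           expr$truth$de_genes$gene,
                           rownames(expr$counts)))
    body_genes <- body_genes[seq_len(cfg$n_gene_bodies)]
    gene_bodies <- domain_set(chrom = "chr1",
                              start = bmid - bw %/% 2L,
                              end = bmid - bw %/% 2L + bw,
                              name = body_genes, class = "gene_body")
  }

  # X chromosome CpG islands
  x_cgi <- NULL
  if (cfg$n_x_cgi > 0) {
    step <- cfg$x_length %/% (cfg$n_x_cgi + 1L)
    st <- step * seq_len(cfg$n_x_cgi)
    x_cgi <- domain_set(chrom = "chrX", start = st,
                        end = st + cfg$x_cgi_kb * 1000,
                        name = sprintf("x_cgi_%02d", seq_len(cfg$n_x_cgi)),
                        class = "x_cgi")
  }

  # site placement (both contexts, both chromosomes)
  sites <- rbind(
    simulate_cpg_sites(cfg$genome_length, cfg$cpg_spacing_mean,
                       "chr1", "CpG"),
    simulate_cpg_sites(cfg$genome_length, cfg$cpg_spacing_mean,
                       "chr1", "CHH"),
    simulate_cpg_sites(cfg$x_length, cfg$cpg_spacing_mean, "chrX", "CpG"),
    simulate_cpg_sites(cfg$x_length, cfg$cpg_spacing_mean, "chrX", "CHH"))

  base_rate <- function(rates) {
    r <- rep(cfg$x_background_rate, nrow(sites))
    on1 <- sites$chrom == "chr1"
    di <- findInterval(sites$pos[on1] - 1L, domains$start)
    di[di < 1L] <- 1L
    r[on1] <- rates[di]
    assign_override <- function(r, regions, rate) {
      if (is.null(regions) || nrow(regions) == 0L) return(r)
      for (k in seq_len(nrow(regions))) {
        hit <- sites$chrom == regions$chrom[k] &
          sites$pos > regions$start[k] & sites$pos <= regions$end[k]
        r[hit] <- rate[k]
      }
      r
    }
    if (!is.null(gdmrs)) r <- assign_override(r, gdmrs, gdmrs$rate)
    if (!is.null(x_cgi))
      r <- assign_override(r, x_cgi, rep(cfg$x_cgi_rate, nrow(x_cgi)))
    r
  }
  rate_young <- base_rate(landscape$rates)
  rate_aged <- base_rate(dmr$rates_aged)

  # per-cell gene-body rates of coupled genes from realised expression
  coupled <- expr$truth$coupled_genes$gene
  z_coupled <- NULL
  if (length(coupled) > 0) {
    ln <- log_normalize(expr$counts, expr$size_factors)[coupled, ,
                                                        drop = FALSE]
    z_coupled <- t(scale(t(ln)))
    z_coupled[is.na(z_coupled)] <- 0
  }
  body_site_idx <- list()
  if (!is.null(gene_bodies)) {
    body_site_idx <- lapply(seq_len(nrow(gene_bodies)), function(k)
      which(sites$chrom == "chr1" &
              sites$pos > gene_bodies$start[k] &
              sites$pos <= gene_bodies$end[k]))
    names(body_site_idx) <- gene_bodies$name
  }

  is_cpg <- sites$context == "CpG"
  noncpg_from <- function(cpg_rate)
    clip01(cfg$noncpg_base + cfg$noncpg_cpg_slope * cpg_rate)

  meth_cells <- list()
  cell_seeds <- sample.int(.Machine$integer.max %/% 2L,
                           nrow(meth_cells_ann))
  coverage <- stats::runif(nrow(meth_cells_ann),
                           cfg$coverage_range[1], cfg$coverage_range[2])
  for (i in seq_len(nrow(meth_cells_ann))) {
    id <- meth_cells_ann$cell_id[i]
    aged <- meth_cells_ann$age_group[i] == "aged"
    r <- if (aged) rate_aged else rate_young
    # cell-specific coupled gene-body rates
    for (g in coupled) {
      idx <- body_site_idx[[g]]
      if (length(idx))
        r[idx] <- clip01(cfg$coupling_base +
                           cfg$coupling_slope * z_coupled[g, id],
                         0.02, 0.98)
    }
    shift <- stats::rnorm(1, 0, cfg$cell_rate_noise_sd) +
      if (aged) cfg$aged_global_shift else 0
    r_cpg <- clip01(r + shift)
    r_site <- ifelse(is_cpg, r_cpg,
                     clip01(noncpg_from(r_cpg) +
                              if (aged) cfg$noncpg_aged_shift else 0))
    meth_cells[[id]] <- simulate_cell_methylome(
      sites, r_site, coverage[i], seed = cell_seeds[i],
      reads_per_site = cfg$reads_per_site)
  }
  meth_cells_ann$coverage_fraction <- coverage
  meth_cells_ann$mapping_efficiency <-
    stats::runif(nrow(meth_cells_ann), 20, 45)

  truth <- c(expr$truth,
             list(true_dmrs = dmr$truth,
                  rates_young = landscape$rates,
                  rates_aged = dmr$rates_aged))

  list(domains = domains, rates_young = landscape$rates,
       rates_aged = dmr$rates_aged, gdmrs = gdmrs, x_cgi = x_cgi,
       gene_bodies = gene_bodies, meth_cells = meth_cells,
       meth_annotation = meth_cells_ann, counts = expr$counts,
       annotation = annotation, size_factors = expr$size_factors,
       truth = truth)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits one Bismark-style coverage file per cell and sequence context
#' (`<cell>.<context>.cov`; the samplesheet's `path` column points at
#' the CpG file), a tab-separated
#' genes x cells count matrix, BED files for domains, gDMRs, gene
#' bodies and X CpG islands, a methylome samplesheet, a transcriptome
#' cell annotation table, and the ground truth as JSON.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov_dir <- file.path(dir, "coverage")
  dir.create(cov_dir, showWarnings = FALSE)
  # the coverage format cannot encode sequence context (it lives in the
  # file name by convention), so each context gets its own file
  for (id in names(dataset$meth_cells)) {
    calls <- dataset$meth_cells[[id]]
    for (ctx in unique(calls$context))
      write_coverage_file(calls[calls$context == ctx, ],
                          file.path(cov_dir, paste0(id, ".", ctx, ".cov")))
  }
  write_count_matrix(dataset$counts, file.path(dir, "counts.tsv"))
  write_bed(dataset$domains, file.path(dir, "domains.bed"))
  if (!is.null(dataset$gdmrs))
    write_bed(dataset$gdmrs, file.path(dir, "gdmrs.bed"))
  if (!is.null(dataset$gene_bodies))
    write_bed(dataset$gene_bodies, file.path(dir, "gene_bodies.bed"))
  if (!is.null(dataset$x_cgi))
    write_bed(dataset$x_cgi, file.path(dir, "x_cgi.bed"))
  ss <- dataset$meth_annotation
  ss$path <- file.path("coverage", paste0(ss$cell_id, ".CpG.cov"))
  utils::write.table(ss, file.path(dir, "samplesheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$annotation,
                     file.path(dir, "cell_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
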