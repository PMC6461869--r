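# table whose OTU abundances have controlled relations to a trait vector
make_screen_fixture <- function() {
  ic50 <- seq(0, 1.4, by = 0.2)                    # 8 samples
  n <- length(ic50)
  weak <- c(30, 35, 28, 33, 31, 29, 34, 30)        # unrelated
  counts <- cbind(
    up    = round(10 + 100 * ic50),                # strictly increasing
    down  = round(150 - 100 * ic50),               # strictly decreasing
    flat  = rep(40, n),                            # zero relative variance
    weak  = weak,
    pad   = 65 - weak                              # keeps row sums constant
  )
  rownames(counts) <- paste0("s", seq_len(n))
  prof <- data.frame(sample_id = rownames(counts), log_ic50 = ic50,
                     ph_opt = rev(ic50) + 5)
  list(tab = otu_table(counts), prof = prof)
}

test_that("the screen classifies monotone, flat and weak OTUs correctly", {
  fx <- make_screen_fixture()
  rep <- screen_otus(fx$tab, fx$prof, abundance_threshold = 0.01,
                     rho_threshold = 0.5)
  r <- setNames(rep$class_salt, rep$otu_id)
  expect_identical(r[["up"]], "positive")
  expect_identical(r[["down"]], "negative")
  expect_identical(r[["flat"]], "none")
  expect_true(rep$degenerate[rep$otu_id == "flat"])
  expect_equal(rep$rho_salt[rep$otu_id == "flat"], 0)
  expect_equal(rep$rho_salt[rep$otu_id == "up"], 1)
  # relative-abundance monotonicity also drives the pH classification
  expect_identical(rep$class_ph[rep$otu_id == "up"], "negative")
})

test_that("classification is a pure threshold function of rho", {
  fx <- make_screen_fixture()
  loose <- screen_otus(fx$tab, fx$prof, rho_threshold = 0.4)
  strict <- screen_otus(fx$tab, fx$prof, rho_threshold = 1)
  # with the threshold at 1 only perfectly monotone OTUs are classified
  expect_setequal(strict$otu_id[strict$class_salt != "none"],
                  c("up", "down"))
  weak_rho <- loose$rho_salt[loose$otu_id == "weak"]
  expect_identical(loose$class_salt[loose$otu_id == "weak"],
                   if (weak_rho >= 0.4) "positive"
                   else if (weak_rho <= -0.4) "negative" else "none")
})

test_that("the screen is invariant to row and column order", {
  fx <- make_screen_fixture()
  base <- screen_otus(fx$tab, fx$prof)
  perm_tab <- otu_table(fx$tab$counts[c(5, 1, 8, 2, 7, 3, 6, 4),
                                      c(3, 1, 5, 4, 2)],
                        fx$tab$taxonomy[c(3, 1, 5, 4, 2)])
  perm <- screen_otus(perm_tab, fx$prof)
  perm <- perm[match(base$otu_id, perm$otu_id), ]
  expect_equal(perm$rho_salt, base$rho_salt)
  expect_identical(perm$class_salt, base$class_salt)
})

test_that("abundance screening and the empty-report path behave as specified", {
  fx <- make_screen_fixture()
  # with an extreme threshold nothing passes: empty report plus warning
  expect_warning(out <- screen_otus(fx$tab, fx$prof,
                                    abundance_threshold = 0.999),
                 "no OTU")
  expect_equal(nrow(out), 0)
  # missing profile rows are an error
  expect_error(screen_otus(fx$tab, fx$prof[-1, ]), "missing")
})

test_that("planted halotolerant taxa are recovered in both gradients and their overlap", {
  md <- generate_gradient_metadata(gradient_design(), seed = 31)
  taxa <- generate_taxa(120, niche_config(), seed = 31)
  planted <- paste0("OTU_", sprintf("%04d", 1:5))
  taxa$salt_logic50[1:5] <- seq(1.3, 1.7, length.out = 5)
  taxa$base_abundance[1:5] <- 4
  taxa$ph_optimum[1:5] <- 6.5        # broad pH generalists: the salt niche
  taxa$ph_breadth[1:5] <- 2.5        # alone drives their distribution
  tab <- generate_otu_table(md, taxa, read_depth = 4000, seed = 31)
  truth <- data.frame(sample_id = md$sample_id, stringsAsFactors = FALSE)
  comp <- expected_composition(md, taxa)
  truth$log_ic50 <- vapply(seq_len(nrow(md)), function(i)
    true_salt_ic50(taxa, comp[i, ]), numeric(1))
  truth$ph_opt <- vapply(seq_len(nrow(md)), function(i)
    true_ph_optimum(taxa, comp[i, ]), numeric(1))
  reports <- lapply(c("AG", "NV"), function(g) {
    ids <- md$sample_id[md$gradient == g]
    screen_otus(otu_table(tab$counts[ids, ], tab$taxonomy), truth)
  })
  for (rep in reports) {
    cls <- setNames(rep$class_salt, rep$otu_id)
    expect_true(all(cls[planted] == "positive"))
    expect_gte(sum(rep$class_salt == "positive"), 5)
  }
  overlap <- cross_gradient_overlap(reports[[1]], reports[[2]],
                                    "salt", "positive")
  expect_true(all(planted %in% overlap))
})

test_that("cross-gradient overlap is a plain class intersection", {
  a <- data.frame(otu_id = c("x", "y", "z"),
                  class_salt = c("positive", "positive", "none"),
                  stringsAsFactors = FALSE)
  b <- data.frame(otu_id = c("x", "y", "z"),
                  class_salt = c("none", "positive", "positive"),
                  stringsAsFactors = FALSE)
  expect_identical(cross_gradient_overlap(a, b, "salt", "positive"), "y")
  expect_identical(cross_gradient_overlap(a, a, "salt", "positive"),
                   c("x", "y"))
  b2 <- b; b2$class_salt <- "none"
  expect_length(cross_gradient_overlap(a, b2, "salt", "positive"), 0)
})

test_that("the cross-trait table conserves counts and shows the confounded pattern", {
  fx <- make_screen_fixture()
  rep <- screen_otus(fx$tab, fx$prof)
  tab <- cross_trait_table(rep)
  expect_equal(sum(tab), nrow(rep))
  allnone <- rep; allnone$class_salt <- "none"; allnone$class_ph <- "none"
  t2 <- cross_trait_table(allnone)
  expect_equal(unname(t2["none", "none"]), nrow(rep))
  expect_error(cross_trait_table(rep[0, ]), "empty")
  # on the EC-pH confounded gradient, salt-positive OTUs are pH-negative
  study <- small_study()
  md <- study$metadata
  nv <- md$sample_id[md$gradient == "NV"]
  nv_rep <- screen_otus(
    otu_table(study$otu$counts[nv, ], study$otu$taxonomy),
    study$truth)
  ct <- cross_trait_table(nv_rep)
  expect_gt(ct["positive", "negative"], ct["positive", "positive"])
})
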