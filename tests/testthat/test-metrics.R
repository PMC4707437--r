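test_that("per-residue Q accuracy counts matching positions", {
  expect_equal(q_accuracy("HHCE", "HHCE"), 100)
  expect_equal(q_accuracy("HHHH", "HHCC"), 50)
  expect_error(q_accuracy("HH", "HHH"), "length")
  # long random pair against a position-by-position count oracle
  set.seed(50)
  a <- paste(sample(c("H", "E", "C"), 1000, replace = TRUE), collapse = "")
  b <- paste(sample(c("H", "E", "C"), 1000, replace = TRUE), collapse = "")
  expect_equal(q_accuracy(a, b),
               100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]))
})

test_that("per-state recall and precision match hand-tabulated counts", {
  perfect <- per_state_scores("HHEECC", "HHEECC")
  expect_true(all(perfect$recall == 1 & perfect$precision == 1))
  # truth all-H, prediction all-E: recall(H) = 0 and precision(E) = 0
  deg <- per_state_scores("EEEE", "HHHH", alphabet = c("H", "E", "C"))
  expect_equal(deg$recall[deg$state == "H"], 0)
  expect_equal(deg$precision[deg$state == "E"], 0)
  # constructed 20-residue confusion case
  truth <- "HHHHHHEEEEEECCCCCCCC"   # H:6 E:6 C:8
  pred  <- "HHHHEEEEEECCCCCCCCHH"   # H TP=4, E TP=2, C TP=6 by position
  tab <- per_state_scores(pred, truth)
  p <- strsplit(pred, "")[[1]]; t <- strsplit(truth, "")[[1]]
  for (s in c("H", "E", "C")) {
    row <- tab[tab$state == s, ]
    expect_equal(row$recall, sum(p == s & t == s) / sum(t == s))
    expect_equal(row$precision, sum(p == s & t == s) / sum(p == s))
    expect_equal(row$support, sum(t == s))
  }
})

test_that("run-length segmentation tiles the string and round-trips", {
  seg <- ss_segments("HHHEEC")
  expect_equal(seg$state, c("H", "E", "C"))
  expect_equal(seg$start, c(0L, 3L, 5L))
  expect_equal(seg$end, c(3L, 5L, 6L))
  expect_equal(ss_segments("EEEE"),
               data.frame(state = "E", start = 0L, end = 4L))
  set.seed(60)
  for (rep in 1:5) {
    s <- paste(sample(c("H", "E", "C"), 40, replace = TRUE), collapse = "")
    seg <- ss_segments(s)
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])   # no gaps/overlaps
    expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
    rebuilt <- paste(unlist(Map(function(st, a, b) rep(st, b - a),
                                seg$state, seg$start, seg$end)),
                     collapse = "")
    expect_equal(rebuilt, s)
  }
  expect_error(ss_segments(""), "empty")
})

test_that("segment overlap score reproduces worked examples", {
  expect_equal(sov("HHHEECCC", "HHHEECCC"), 100)
  # one 10-residue helix, half predicted: minov 5, maxov 10, delta 2 -> 70
  expect_equal(sov("HHHHHCCCCC", "HHHHHHHHHH"), 70)
  expect_equal(sov("CCCC", "HHHH"), 0)
  expect_error(sov("HH", "HHH"), "length")
})

test_that("segment overlap score is bounded and relabeling-invariant", {
  set.seed(70)
  for (rep in 1:20) {
    a <- paste(sample(c("H", "E", "C"), 30, replace = TRUE,
                      prob = c(0.4, 0.3, 0.3)), collapse = "")
    b <- paste(sample(c("H", "E", "C"), 30, replace = TRUE), collapse = "")
    s <- sov(b, a)
    expect_gte(s, 0); expect_lte(s, 100)
    # consistent relabeling H<->E in both strings leaves the score unchanged
    swap <- function(x) chartr("HE", "EH", x)
    expect_equal(sov(swap(b), swap(a)), s, tolerance = 1e-12)
  }
})

test_that("mid-segment errors cost at least as much as terminal ones", {
  # single 12-residue helix in coil context; 2 residues wrongly predicted
  truth <- paste0("CCC", strrep("H", 12), "CCC")
  mid <- paste0("CCC", "HHHHH", "CC", "HHHHH", "CCC")    # middle break
  ends <- paste0("CCC", "CC", strrep("H", 10), "CCC")    # trimmed start
  expect_equal(q_accuracy(mid, truth), q_accuracy(ends, truth))
  expect_lte(sov(mid, truth), sov(ends, truth))
})

test_that("three-state accuracy dominates eight-state accuracy", {
  set.seed(80)
  for (rep in 1:10) {
    truth <- paste(sample(c("H","G","I","E","B","T","S","L"), 60,
                          replace = TRUE), collapse = "")
    pred <- paste(sample(c("H","G","I","E","B","T","S","L"), 60,
                         replace = TRUE), collapse = "")
    expect_gte(q_accuracy(ss8_to_ss3(pred), ss8_to_ss3(truth)),
               q_accuracy(pred, truth))
  }
})

test_that("evaluation reports bundle the metrics and serialize", {
  truth <- c("HHHHGGEEEELLLL", "TTSSEEEEBBHHHH")
  pred <- c("HHHHHHEEEELLLL", "TTTTEEEEEEHHHH")
  rep8 <- evaluate_predictions(pred, truth, states = 8)
  expect_equal(rep8$q8, q_accuracy(pred, truth))
  expect_equal(rep8$q3, q_accuracy(ss8_to_ss3(pred), ss8_to_ss3(truth)))
  expect_gte(rep8$q3, rep8$q8)
  expect_equal(nrow(rep8$per_state), 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep8, path)
  tab <- read.delim(path)
  expect_equal(tab$value[tab$metric == "Q8"], rep8$q8, tolerance = 1e-4)
  expect_true(file.exists(sub("\\.tsv$", ".json", path)))
})
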