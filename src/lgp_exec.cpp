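#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Program encoding: numeric matrix, one row per instruction, 7 columns:
//   0 kind      0 = assignment, 1 = branch
//   1 dest      calculation-register index (0-based; -1 for branches)
//   2 op        assignment: 1 '+', 2 '-', 3 '*', 4 '/', 5 '^'
//               branch:     1 '<', 2 '>'
//   3 lhs_type  0 = feature register, 1 = calculation register, 2 = constant
//   4 lhs_val   register index (0-based) or constant value
//   5 rhs_type  as lhs_type
//   6 rhs_val   as lhs_val

static inline double protected_op(int op, double a, double b) {
  double r;
  switch (op) {
  case 1: r = a + b; break;
  case 2: r = a - b; break;
  case 3: r = a * b; break;
  case 4:
    // protected division: near-zero denominator yields the neutral value 1
    if (std::fabs(b) < 1e-9) return 1.0;
    r = a / b;
    break;
  case 5:
    // protected power: |a|^b, magnitude capped at 1e6, 1 on overflow/NaN
    r = std::pow(std::fabs(a), b);
    if (!std::isfinite(r)) return 1.0;
    if (r > 1e6) r = 1e6;
    return r;
  default: return 1.0;
  }
  // totality guard: overflow of +,-,* collapses to the neutral value
  if (!std::isfinite(r)) return 1.0;
  return r;
}

static inline double operand_value(int type, double val, const double* feat,
                                   const std::vector<double>& r) {
  if (type == 0) return feat[(int)val];
  if (type == 1) return r[(int)val];
  return val;
}

// Execute a program on every row of X; returns the final r[0] per sample.
// [[Rcpp::export]]
NumericVector cpp_execute_batch(NumericMatrix prog, NumericMatrix X,
                                int n_calc) {
  const int n = prog.nrow();
  const int ns = X.nrow();
  const int nf = X.ncol();
  NumericVector out(ns);
  std::vector<double> r((size_t)n_calc);
  std::vector<double> feat((size_t)std::max(nf, 1));
  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < nf; ++j) feat[j] = X(s, j);
    std::fill(r.begin(), r.end(), 1.0);
    int i = 0;
    while (i < n) {
      const int kind = (int)prog(i, 0);
      const double a =
          operand_value((int)prog(i, 3), prog(i, 4), feat.data(), r);
      const double b =
          operand_value((int)prog(i, 5), prog(i, 6), feat.data(), r);
      if (kind == 0) {
        r[(int)prog(i, 1)] = protected_op((int)prog(i, 2), a, b);
        ++i;
      } else {
        const bool cond = ((int)prog(i, 2) == 1) ? (a < b) : (a > b);
        if (cond) {
          ++i;
        } else {
          // skip the whole chain of following branches plus the single
          // instruction the chain guards
          int j = i + 1;
          while (j < n && (int)prog(j, 0) == 1) ++j;
          i = j + 1;
        }
      }
    }
    out[s] = r[0];
  }
  return out;
}

LogicalVector cpp_effective_mask(NumericMatrix prog, int n_calc);
NumericVector cpp_eval_program(NumericMatrix prog, NumericMatrix X,
                               LogicalVector labels, int n_calc);

// ---- offspring generation (tournament + recombination + mutation) ----------
// Uses R's RNG (unif_rand) so runs remain a pure function of the R seed.

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void rand_operand(double* type, double* val, int nf, int ncalc,
                         const NumericVector& consts,
                         const NumericVector& opp) {
  double u = unif_rand();
  if (u < opp[0]) {
    *type = 0; *val = rand_below(nf);
  } else if (u < opp[0] + opp[1]) {
    *type = 1; *val = rand_below(ncalc);
  } else {
    *type = 2; *val = consts[rand_below(consts.size())];
  }
}

static NumericMatrix mutate_code(const NumericMatrix& code, int nf, int ncalc,
                                 const NumericVector& consts,
                                 const NumericVector& opp) {
  NumericMatrix out = clone(code);
  const int n = out.nrow();
  LogicalVector eff = cpp_effective_mask(out, ncalc);
  std::vector<int> pool;
  for (int i = 0; i < n; ++i)
    if (eff[i]) pool.push_back(i);
  if (pool.empty())
    for (int i = 0; i < n; ++i) pool.push_back(i);
  const int i = pool[rand_below((int)pool.size())];
  const bool branch = (int)out(i, 0) == 1;
  // element menu: operands always; comparator for branches; operator and
  // (when there is more than one calc register) destination for assignments
  int n_elems = branch ? 3 : (ncalc > 1 ? 4 : 3);
  int e = rand_below(n_elems);
  if (branch && e == 2) {
    out(i, 2) = 3 - out(i, 2);
  } else if (!branch && e == 2) {
    int op;
    do { op = 1 + rand_below(5); } while (op == (int)out(i, 2));
    out(i, 2) = op;
  } else if (!branch && e == 3) {
    int d;
    do { d = rand_below(ncalc); } while (d == (int)out(i, 1));
    out(i, 1) = d;
  } else {
    const int c0 = (e == 0) ? 3 : 5;
    double type, val;
    for (int t = 0; t < 100; ++t) {
      rand_operand(&type, &val, nf, ncalc, consts, opp);
      if (type != out(i, c0) || val != out(i, c0 + 1)) break;
    }
    out(i, c0) = type;
    out(i, c0 + 1) = val;
  }
  return out;
}

static void copy_rows(NumericMatrix& dst, int at, const NumericMatrix& src,
                      int from, int len) {
  for (int r = 0; r < len; ++r)
    for (int c = 0; c < 7; ++c) dst(at + r, c) = src(from + r, c);
}

static bool recombine_codes(const NumericMatrix& a, const NumericMatrix& b,
                            int lo, int hi, NumericMatrix& c1,
                            NumericMatrix& c2) {
  const int n1 = a.nrow(), n2 = b.nrow();
  for (int t = 0; t < 200; ++t) {
    const int s1 = 1 + rand_below(n1 + 1);
    const int e1 = (s1 > n1) ? s1 - 1 : (s1 - 1) + rand_below(n1 - s1 + 2);
    const int s2 = 1 + rand_below(n2 + 1);
    const int e2 = (s2 > n2) ? s2 - 1 : (s2 - 1) + rand_below(n2 - s2 + 2);
    const int l1 = e1 - s1 + 1, l2 = e2 - s2 + 1;
    const int m1 = n1 - l1 + l2, m2 = n2 - l2 + l1;
    if (m1 < lo || m1 > hi || m2 < lo || m2 > hi) continue;
    c1 = NumericMatrix(m1, 7);
    c2 = NumericMatrix(m2, 7);
    copy_rows(c1, 0, a, 0, s1 - 1);
    copy_rows(c1, s1 - 1, b, s2 - 1, l2);
    copy_rows(c1, s1 - 1 + l2, a, e1, n1 - e1);
    copy_rows(c2, 0, b, 0, s2 - 1);
    copy_rows(c2, s2 - 1, a, s1 - 1, l1);
    copy_rows(c2, s2 - 1 + l1, b, e2, n2 - e2);
    return true;
  }
  return false;
}

// One generation of offspring: tournament parent selection over `fit`,
// segment recombination, single-element mutation of an effective
// instruction, and fused fitness evaluation.  Returns list(codes, fit, neff).
// [[Rcpp::export]]
List cpp_offspring(List pop, NumericVector fit, NumericMatrix X,
                   LogicalVector labels, int lambda, int tournament,
                   double recomb_rate, double mut_rate, bool both,
                   int min_len, int max_len, int nf, int ncalc,
                   NumericVector consts, NumericVector operand_probs) {
  const int mu = pop.size();
  List codes(lambda);
  NumericVector ofit(lambda), oneff(lambda);
  std::vector<NumericMatrix> kids;
  kids.reserve(2);
  int k = 0;
  while (k < lambda) {
    kids.clear();
    if (unif_rand() < recomb_rate) {
      int ia = 0, ib = 0;
      for (int t = 0; t < tournament; ++t) {
        int c = rand_below(mu);
        if (t == 0 || fit[c] < fit[ia]) ia = c;
      }
      for (int t = 0; t < tournament; ++t) {
        int c = rand_below(mu);
        if (t == 0 || fit[c] < fit[ib]) ib = c;
      }
      NumericMatrix c1, c2;
      if (recombine_codes(pop[ia], pop[ib], min_len, max_len, c1, c2)) {
        kids.push_back(c1);
        if (both) kids.push_back(c2);
      } else {
        kids.push_back(clone(as<NumericMatrix>(pop[ia])));
        if (both) kids.push_back(clone(as<NumericMatrix>(pop[ib])));
      }
    } else {
      int ia = 0;
      for (int t = 0; t < tournament; ++t) {
        int c = rand_below(mu);
        if (t == 0 || fit[c] < fit[ia]) ia = c;
      }
      kids.push_back(as<NumericMatrix>(pop[ia]));
    }
    for (size_t j = 0; j < kids.size() && k < lambda; ++j) {
      NumericMatrix kid = kids[j];
      if (unif_rand() < mut_rate) {
        kid = mutate_code(kid, nf, ncalc, consts, operand_probs);
      }
      NumericVector e = cpp_eval_program(kid, X, labels, ncalc);
      codes[k] = kid;
      ofit[k] = e[0];
      oneff[k] = e[1];
      ++k;
    }
  }
  return List::create(_["codes"] = codes, _["fit"] = ofit,
                      _["neff"] = oneff);
}

// Fitness evaluation fused with the effective-instruction count: returns
// c(MCE, n_effective) for one program against a labelled sample matrix.
// [[Rcpp::export]]
NumericVector cpp_eval_program(NumericMatrix prog, NumericMatrix X,
                               LogicalVector labels, int n_calc) {
  NumericVector out = cpp_execute_batch(prog, X, n_calc);
  const int ns = out.size();
  int wrong = 0;
  for (int s = 0; s < ns; ++s) {
    const bool pred = out[s] >= 0.0;
    if (pred != (bool)labels[s]) ++wrong;
  }
  LogicalVector eff = cpp_effective_mask(prog, n_calc);
  int ne = 0;
  for (int i = 0; i < eff.size(); ++i)
    if (eff[i]) ++ne;
  return NumericVector::create((double)wrong / ns, (double)ne);
}

// Backward structural reachability from r[0].  An assignment is effective iff
// its destination is needed; its destination leaves the needed set only when
// the write is unconditional (not guarded by a preceding branch).  A branch is
// effective iff the first non-branch instruction after it is effective.
// [[Rcpp::export]]
LogicalVector cpp_effective_mask(NumericMatrix prog, int n_calc) {
  const int n = prog.nrow();
  LogicalVector eff(n);
  std::vector<char> needed((size_t)n_calc, 0);
  needed[0] = 1;
  for (int i = n - 1; i >= 0; --i) {
    const int kind = (int)prog(i, 0);
    bool is_eff = false;
    if (kind == 1) {
      int j = i + 1;
      while (j < n && (int)prog(j, 0) == 1) ++j;
      is_eff = (j < n) && eff[j];
    } else {
      const int dest = (int)prog(i, 1);
      if (needed[dest]) {
        is_eff = true;
        const bool guarded = (i > 0) && ((int)prog(i - 1, 0) == 1);
        if (!guarded) needed[dest] = 0;
      }
    }
    if (is_eff) {
      eff[i] = true;
      if ((int)prog(i, 3) == 1) needed[(int)prog(i, 4)] = 1;
      if ((int)prog(i, 5) == 1) needed[(int)prog(i, 6)] = 1;
    }
  }
  return eff;
}
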