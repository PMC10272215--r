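#ifndef SEMWALK_RNG_H
#define SEMWALK_RNG_H

#include <cstdint>

// Small deterministic PRNG, independent of R's RNG state so that walk and
// embedding sampling reproduce exactly from an integer seed regardless of
// what the calling R session has done.

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) {
    uint64_t st = seed;
    s = splitmix64(st);
    if (s == 0) s = 0x9E3779B97f4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t x = s;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    s = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  // uniform double in [0, 1)
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform integer in [0, n)
  inline int unif_int(int n) {
    return (int)(unif() * n);
  }
};

#endif
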