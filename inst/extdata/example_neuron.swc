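# synthetic example neuron (not a real reconstruction)
# id type x y z radius parent
1 1 0 0 0 2 -1
2 3 12 2 0 1 1
3 3 25 3 1 1 2
4 3 38 2 3 1 3
5 3 52 0 6 1 4
6 3 66 -3 8 1 5
7 3 80 -5 9 1 6
8 3 64 12 10 1 5
9 3 75 20 13 1 8
10 3 88 26 15 1 9
11 3 30 -8 2 1 3
12 3 36 -18 4 1 11
13 3 40 -29 5 1 12
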