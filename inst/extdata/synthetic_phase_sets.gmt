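G1S	synthetic G1/S phase program matching the generator gene names	g1s.1	g1s.2	g1s.3	g1s.4	g1s.5	g1s.6	g1s.7	g1s.8	g1s.9	g1s.10
G2M	synthetic G2/M phase program matching the generator gene names	g2m.1	g2m.2	g2m.3	g2m.4	g2m.5	g2m.6	g2m.7	g2m.8	g2m.9	g2m.10
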