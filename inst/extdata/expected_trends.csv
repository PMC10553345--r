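system,avg_degree,avg_pagerank,avg_clustering,avg_triangles
ann,Down,,,Down
topic,Up,Down,Down,Up
er_growth,Up,Down,,Up
animal,Up,Down,,Up
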