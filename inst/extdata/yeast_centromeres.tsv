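chrom	cen_start	cen_end
chrI	151465	151582
chrII	238207	238323
chrIII	114385	114501
chrIV	449711	449829
chrV	151987	152104
chrVI	148510	148627
chrVII	496920	497038
chrVIII	105586	105703
chrIX	355629	355745
chrX	436307	436425
chrXI	440129	440246
chrXII	150828	150947
chrXIII	268031	268149
chrXIV	628758	628875
chrXV	326584	326702
chrXVI	555957	556073
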