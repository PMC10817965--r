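site_id	chrom	position	copies
I-1	chrI	33531	1
I-2	chrI	115109	1
I-3	chrI	196687	1
II-1	chrII	118439	1
II-2	chrII	182473	1
II-3	chrII	246507	2
II-4	chrII	310541	1
II-5	chrII	374575	1
II-6	chrII	438609	1
II-7	chrII	502643	1
II-8	chrII	566677	1
II-9	chrII	630711	1
II-10	chrII	694745	1
III-1	chrIII	46115	1
III-2	chrIII	270505	1
IV-1	chrIV	223123	1
IV-2	chrIV	313597	1
IV-3	chrIV	404071	1
IV-4	chrIV	494545	1
IV-5	chrIV	585019	3
IV-6	chrIV	675493	1
IV-7	chrIV	765966	1
IV-8	chrIV	856440	1
IV-9	chrIV	946914	1
IV-10	chrIV	1037388	1
IV-11	chrIV	1127862	1
IV-12	chrIV	1218336	1
IV-13	chrIV	1308810	1
V-1	chrV	84020	1
V-2	chrV	220298	1
V-3	chrV	356576	1
V-4	chrV	492854	1
VI-1	chrVI	39348	1
VI-2	chrVI	135080	1
VI-3	chrVI	230813	1
VII-1	chrVII	158893	1
VII-2	chrVII	545470	2
VII-3	chrVII	932047	1
VIII-1	chrVIII	81948	1
VIII-2	chrVIII	214864	1
VIII-3	chrVIII	347779	1
VIII-4	chrVIII	480695	1
IX-1	chrIX	64069	1
IX-2	chrIX	167986	1
IX-3	chrIX	271902	1
IX-4	chrIX	375819	1
X-1	chrX	108617	1
X-2	chrX	196703	1
X-3	chrX	284789	1
X-4	chrX	372876	2
X-5	chrX	460962	1
X-6	chrX	549048	1
X-7	chrX	637134	1
XI-1	chrXI	97120	1
XI-2	chrXI	569696	1
XII-1	chrXII	157034	1
XII-2	chrXII	411737	2
XII-3	chrXII	666440	1
XII-4	chrXII	921143	1
XIII-1	chrXIII	134641	1
XIII-2	chrXIII	243833	1
XIII-3	chrXIII	353024	1
XIII-4	chrXIII	462216	1
XIII-5	chrXIII	571407	2
XIII-6	chrXIII	680598	1
XIII-7	chrXIII	789790	1
XIV-1	chrXIV	114236	1
XIV-2	chrXIV	670097	1
XV-1	chrXV	158944	1
XV-2	chrXV	416745	1
XV-3	chrXV	674546	2
XV-4	chrXV	932347	1
XVI-1	chrXVI	138084	1
XVI-2	chrXVI	474033	1
XVI-3	chrXVI	809982	1
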