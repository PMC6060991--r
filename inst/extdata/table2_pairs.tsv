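number	mirna_id	mirna_direction	target_gene	target_direction
1	osa-miR156l	Up	LOC_Os02g34860.1	Down
1	osa-miR156l	Up	LOC_Os03g26044.1	Down
1	osa-miR156l	Up	LOC_Os09g31970.1	Down
1	osa-miR156l	Up	LOC_Os04g34570.1	Down
1	osa-miR156l	Up	LOC_Os01g06550.1	Down
1	osa-miR156l	Up	LOC_Os07g29224.1	Down
1	osa-miR156l	Up	LOC_Os03g24960.1	Down
1	osa-miR156l	Up	LOC_Os06g05790.1	Down
2	osa-miR530-5p	Up	LOC_Os04g56980.1	Down
2	osa-miR530-5p	Up	LOC_Os03g17570.6	Down
2	osa-miR530-5p	Up	LOC_Os04g02880.1	Down
3	oru-miR135	Up	LOC_Os05g27930.1	Down
3	oru-miR135	Up	LOC_Os01g67240.1	Down
3	oru-miR135	Up	LOC_Os03g41080.1	Down
3	oru-miR135	Up	LOC_Os07g38800.1	Down
3	oru-miR135	Up	LOC_Os08g23180.1	Down
3	oru-miR135	Up	LOC_Os11g45740.1	Down
4	oru-miR139	Up	LOC_Os01g10580.1	Down
4	oru-miR139	Up	LOC_Os01g13760.1	Down
4	oru-miR139	Up	LOC_Os01g32130.1	Down
5	oru-miR177	Up	LOC_Os09g39462.1	Down
6	oru-miR180	Up	LOC_Os06g24070.1	Down
6	oru-miR180	Up	LOC_Os01g31890.1	Down
6	oru-miR180	Up	LOC_Os01g31940.1	Down
6	oru-miR180	Up	LOC_Os01g55450.1	Down
6	oru-miR180	Up	LOC_Os02g47510.1	Down
6	oru-miR180	Up	LOC_Os01g26000.1	Down
7	osa-miR160f	Down	LOC_Os04g43910.1	Up
7	osa-miR160f	Down	LOC_Os06g49840.1	Up
7	osa-miR160f	Down	LOC_Os02g39080.1	Up
7	osa-miR160f	Down	LOC_Os10g31864.1	Up
8	osa-miR164a	Down	LOC_Os05g18604.1	Up
8	osa-miR164a	Down	LOC_Os08g10080.1	Up
8	osa-miR164a	Down	LOC_Os01g62660.1	Up
8	osa-miR164a	Down	LOC_Os12g05260.1	Up
8	osa-miR164a	Down	LOC_Os09g08130.2	Up
8	osa-miR164a	Down	LOC_Os02g19924.1	Up
8	osa-miR164a	Down	LOC_Os06g46270.1	Up
8	osa-miR164a	Down	LOC_Os06g49660.1	Up
8	osa-miR164a	Down	LOC_Os09g37700.1	Up
8	osa-miR164a	Down	LOC_Os04g38720.1	Up
8	osa-miR164a	Down	LOC_Os12g41680.1	Up
9	osa-miR164b	Down	LOC_Os12g05260.1	Up
9	osa-miR164b	Down	LOC_Os06g46270.1	Up
9	osa-miR164b	Down	LOC_Os06g49660.1	Up
9	osa-miR164b	Down	LOC_Os04g38720.1	Up
10	osa-miR164d	Down	LOC_Os08g10080.1	up
10	osa-miR164d	Down	LOC_Os12g05260.1	up
10	osa-miR164d	Down	LOC_Os09g08130.2	up
10	osa-miR164d	Down	LOC_Os06g46270.1	up
10	osa-miR164d	Down	LOC_Os06g49660.1	up
11	osa-miR164f	Down	LOC_Os06g46270.1	Up
11	osa-miR164f	Down	LOC_Os12g41680.1	Up
11	osa-miR164f	Down	LOC_Os12g05260.1	Up
11	osa-miR164f	Down	LOC_Os04g41540.1	Up
12	osa-miR166a	Down	LOC_Os04g48290.1	Up
13	osa-miR166b	Down	LOC_Os08g34740.1	Up
14	osa-miR166d	Down	LOC_Os08g34740.1	Up
15	osa-miR166f	Down	LOC_Os08g34740.1	Up
16	osa-miR166m	Down	LOC_Os04g48290.1	Up
17	osa-miR167d	Down	LOC_Os06g03830.1	Up
18	osa-miR167f	Down	LOC_Os06g03830.1	Up
19	osa-miR167h	Down	LOC_Os03g29240.1	Up
20	osa-miR172a	Down	LOC_Os03g60430.2	Up
20	osa-miR172a	Down	LOC_Os03g47650.1	Up
20	osa-miR172a	Down	LOC_Os02g56320.1	Up
20	osa-miR172a	Down	LOC_Os06g49500.3	Up
20	osa-miR172a	Down	LOC_Os04g55560.4	Up
21	osa-miR172b	Down	LOC_Os04g55560.2	Up
22	osa-miR172d	Down	LOC_Os06g06050.1	Up
22	osa-miR172d	Down	LOC_Os04g05650.1	Up
23	osa-miR2123c	Down	LOC_Os02g49880.1	Up
24	osa-miR390	Down	LOC_Os02g10100.1	Up
24	osa-miR390	Down	LOC_Os06g03970.1	Up
24	osa-miR390	Down	LOC_Os01g33110.1	Up
24	osa-miR390	Down	LOC_Os02g10100.1	Up
24	osa-miR390	Down	LOC_Os05g33160.1	Up
24	osa-miR390	Down	LOC_Os06g03970.1	Up
24	osa-miR390	Down	LOC_Os04g45170.1	Up
25	osa-miR408	Down	LOC_Os03g15600.1	Up
25	osa-miR408	Down	LOC_Os09g36860.1	Up
25	osa-miR408	Down	LOC_Os08g37670.1	Up
25	osa-miR408	Down	LOC_Os01g54430.1	Up
26	osa-miR5161	Down	LOC_Os05g47560.1	Up
26	osa-miR5161	Down	LOC_Os05g03884.1	Up
26	osa-miR5161	Down	LOC_Os11g01074.1	Up
26	osa-miR5161	Down	LOC_Os03g64320.1	Up
27	osa-miR818b	Down	LOC_Os01g10580.1	Up
27	osa-miR818b	Down	LOC_Os10g11200.1	Up
27	osa-miR818b	Down	LOC_Os02g54640.1	Up
27	osa-miR818b	Down	LOC_Os05g03640.1	Up
28	oru-miR4	Down	LOC_Os05g31530.1	Up
28	oru-miR4	Down	LOC_Os09g39410.1	Up
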