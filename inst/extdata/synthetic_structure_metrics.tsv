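id	set_label	metric_name	value_subnet	value_baseline
dom001	suppression	RMSD	7.541	5.659
dom002	suppression	RMSD	7.077	5.748
dom003	suppression	RMSD	3.051	3.145
dom004	suppression	RMSD	5.358	5.322
dom005	suppression	RMSD	6.859	4.567
dom006	suppression	RMSD	5.392	4.076
dom007	suppression	RMSD	5.377	4.946
dom008	suppression	RMSD	3.936	2.539
dom009	suppression	RMSD	6.857	4.628
dom010	suppression	RMSD	7.457	4.82
dom011	suppression	RMSD	5.073	3.831
dom012	suppression	RMSD	6.222	4.876
dom013	maintenance	RMSD	5.861	5.739
dom014	maintenance	RMSD	2.374	3.022
dom015	maintenance	RMSD	4.02	3.849
dom016	maintenance	RMSD	5.768	5.76
dom017	maintenance	RMSD	6.059	5.913
dom018	maintenance	RMSD	2.715	2.47
dom019	maintenance	RMSD	4.35	3.9
dom020	maintenance	RMSD	4.159	4.241
dom021	maintenance	RMSD	6.042	5.616
dom022	maintenance	RMSD	2.739	2.555
dom023	maintenance	RMSD	6.316	5.956
dom024	maintenance	RMSD	6.117	5.787
dom025	maintenance	RMSD	2.61	2.33
dom026	maintenance	RMSD	3.896	4.057
dom027	maintenance	RMSD	3.638	3.561
dom028	maintenance	RMSD	5.879	5.623
dom029	maintenance	RMSD	3.65	3.788
dom030	maintenance	RMSD	5.308	5.344
dom001	suppression	TM-score	0.538	0.802
dom002	suppression	TM-score	0.512	0.663
dom003	suppression	TM-score	0.604	0.823
dom004	suppression	TM-score	0.425	0.688
dom005	suppression	TM-score	0.675	0.788
dom006	suppression	TM-score	0.694	0.822
dom007	suppression	TM-score	0.504	0.616
dom008	suppression	TM-score	0.468	0.56
dom009	suppression	TM-score	0.412	0.597
dom010	suppression	TM-score	0.569	0.788
dom011	suppression	TM-score	0.625	0.877
dom012	suppression	TM-score	0.5	0.743
dom013	maintenance	TM-score	0.751	0.761
dom014	maintenance	TM-score	0.575	0.619
dom015	maintenance	TM-score	0.684	0.737
dom016	maintenance	TM-score	0.636	0.613
dom017	maintenance	TM-score	0.702	0.708
dom018	maintenance	TM-score	0.615	0.661
dom019	maintenance	TM-score	0.595	0.591
dom020	maintenance	TM-score	0.607	0.615
dom021	maintenance	TM-score	0.798	0.805
dom022	maintenance	TM-score	0.711	0.694
dom023	maintenance	TM-score	0.698	0.695
dom024	maintenance	TM-score	0.709	0.718
dom025	maintenance	TM-score	0.702	0.7
dom026	maintenance	TM-score	0.555	0.598
dom027	maintenance	TM-score	0.843	0.839
dom028	maintenance	TM-score	0.76	0.757
dom029	maintenance	TM-score	0.797	0.828
dom030	maintenance	TM-score	0.841	0.819
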