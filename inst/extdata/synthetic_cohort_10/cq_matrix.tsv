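sample_id	UniSp2	UniSp4	UniSp6	miR-23a	miR-451a	miR-93-5p	miR-1246	miR-223-3p	let-7g-5p	miR-21-5p	cand-01	cand-02	cand-03
S0001	20.3640142575549	23.1168691280776	18.2057796588426	26.2778954301058	23.4372794337991	22.7692254034029	31.7901626932188	28.1876184886565	33.2545105151375	28.1228961333641	31.7287810714682	34.2516209193975	32.7351193109208
S0002	20.7268776876209	28.9092887484468	18.0319963316948	26.486603411501	25.1371863719616	22.7797250907236	31.436636576744	28.2589201040692	31.0207489369909	27.5733714292488	33.4451062786225	34.6935199874069	31.3560278059862
S0003	21.2567640806919	26.9923914034989	18.146022398077	25.5832893042503	24.3668940194518	23.1302753545564	31.9176112948135	28.2799419797258	30.9149867008127	27.2835399277048	32.3253426752193	34.4959502795015	31.4796631268925
S0004	22.2465768659831	31.1423371732957	18.0628706978765	25.5253069878891	25.5170647110099	23.209289054531	31.9002914401253	28.331063264438	30.6807677109714	28.4699234242616	31.1258891299857	35.0545846199863	30.8192758390589
S0005	23.9999377914039	26.3424454199927	18.1360557256674	26.6491765087297	23.4040517683932	23.1634348199607	31.745568515855	28.2349162595414	32.4366175916418	27.7033144527273	34.1036939359023	34.7102873491281	31.0970884060953
S0006	24.9211178507388	28.180947299978	18.0910272894064	25.9192007492591	23.3345235940018	22.8283054862929	31.8842475097156	28.1946198180136	30.4901355897561	28.1593501942363	29.1450665596514	32.5080549215299	32.9579033946286
S0007	22.7416746244671	28.8218301585147	18.1951781580064	25.7911074804095	24.175522551481	22.8983052281865	32.0751319705108	28.3709343716851	31.1267046180104	26.6895216737678	33.2781002975523	35.8809746682037	30.457885546971
S0008	22.3487106778657	31.0239379936843	18.3397750287459	27.3278535305572	19.0795390688864	22.8483268485338	31.9499481099299	28.0930496313319	30.9811854591016	28.2134636930041	32.2437637408949	35.0637273545593	31.7681595832988
S0009	23.9068616754582	28.4211602700108	17.9729960016304	25.6239222207279	23.7611684346238	23.0184238875604	31.9105933462032	28.2106284711712	31.6889468449025	28.3957443750456	32.3370446816506	32.150781262388	30.5526059094373
S0010	25.1678003183848	27.5972013754133	17.9137238647109	25.5370545063609	23.5854953504866	22.957586276525	32.0299197917577	28.3862597395067	32.4707580351459	28.2039118579139	32.9544178002053	32.225883399398	33.0124378025657
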