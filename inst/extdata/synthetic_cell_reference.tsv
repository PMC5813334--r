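probe_id	Gran	CD4T	CD8T	Bcell	NK	Mono
ct_marker_001	0.947874404361937	0.0749493072647601	0.118956968737766	0.17337763041025	0.0578008576808497	0.0969345110235736
ct_marker_002	0.939046056370716	0.115570934836287	0.111506887325086	0.0884919722401537	0.0670188615401276	0.134412074764259
ct_marker_003	0.948503055167384	0.149299246389419	0.123219475306105	0.0837124311830849	0.172431365856901	0.162286844337359
ct_marker_004	0.883440621336922	0.140176953193732	0.0787581863510422	0.170116617355961	0.144267579566222	0.0937324029160664
ct_marker_005	0.930767752649262	0.12072704447899	0.141866729366593	0.145165100710001	0.148073973075952	0.0736970318225212
ct_marker_006	0.912866151146591	0.135681339413859	0.0917550460598432	0.146164031797089	0.109078860713635	0.0700059741013683
ct_marker_007	0.863646203232929	0.11093468940584	0.148739542094991	0.127146727845538	0.105837225918658	0.104317462407053
ct_marker_008	0.863210376433562	0.112634720068891	0.0708346336148679	0.0604339870205149	0.142108509596437	0.0875333257811144
ct_marker_009	0.902382667851634	0.0938182677980512	0.131266255844384	0.154177231097128	0.14971789364703	0.147680331834126
ct_marker_010	0.818307752069086	0.105188419218175	0.064080883723218	0.0839506546827033	0.0864076885860413	0.122352598377038
ct_marker_011	0.0723272499837913	0.843907019216567	0.16262404151028	0.0868034909316339	0.171861087472644	0.0776245890092105
ct_marker_012	0.0800920232338831	0.829773979668971	0.151224922842812	0.142840421707369	0.0562065752106719	0.157686173715629
ct_marker_013	0.150465552948881	0.928165338933468	0.151282884336542	0.162867956995033	0.140190708236769	0.0572467417945154
ct_marker_014	0.0625192004162818	0.807362815388478	0.115661139027216	0.141171995874029	0.144638386035804	0.157152079222724
ct_marker_015	0.108948210112285	0.899906949396245	0.163833458304871	0.0580314054316841	0.116728136665188	0.164538983847015
ct_marker_016	0.0610110926814377	0.859616975928657	0.135485707083717	0.106863421527669	0.094014454788994	0.15574419910321
ct_marker_017	0.122886562717613	0.805157423159108	0.166517511075363	0.0929842702229507	0.0592447092104703	0.165602993005887
ct_marker_018	0.0511315979901701	0.824501718359534	0.155237569990568	0.167546666439157	0.137886326278094	0.105534138251096
ct_marker_019	0.178145821790677	0.836671426275279	0.148570029067341	0.107215190373827	0.159971673295368	0.11443423305871
ct_marker_020	0.0911560245323926	0.864209938049316	0.154715027364437	0.100046133145224	0.105298713662196	0.155559322773479
ct_marker_021	0.133128362449352	0.165504035828635	0.804003553220537	0.140758196578827	0.0859420159296133	0.132569393878803
ct_marker_022	0.088379020600114	0.164210272938944	0.904160826373845	0.163615129194222	0.0741840651701205	0.175613392579835
ct_marker_023	0.179571480203886	0.0814830031944439	0.933019641949795	0.143805316053331	0.152923828959465	0.119877672372386
ct_marker_024	0.167782771633938	0.146388993621804	0.929228982049972	0.107466776159126	0.0880612804437988	0.0718802247662097
ct_marker_025	0.178536088727415	0.100395320737734	0.858518358692527	0.110889900417533	0.15488412136212	0.115352317574434
ct_marker_026	0.0585339461266995	0.0602637260407209	0.851593116403092	0.162622626300436	0.089499917072244	0.172744339471683
ct_marker_027	0.13151503860252	0.0623286215076223	0.820488023455255	0.065616280012764	0.133678181644063	0.150248848078772
ct_marker_028	0.113761755311862	0.149078555044252	0.853374233143404	0.0521159994462505	0.120662320845295	0.129894039612263
ct_marker_029	0.176233173676301	0.0952262233453803	0.868895675404929	0.130760360094719	0.163330676706973	0.160673862276599
ct_marker_030	0.0970887101767585	0.104179672163446	0.930538472009357	0.108560962013435	0.115895917031448	0.091599197241012
ct_marker_031	0.138399149945471	0.0947221099864692	0.0620180416060612	0.895919403235894	0.0791843750886619	0.0987156060663983
ct_marker_032	0.0842835909407586	0.0510934199532494	0.167477064242121	0.871624654531479	0.142056709332392	0.169851758726873
ct_marker_033	0.0741428539785557	0.168504748793785	0.0743089172430337	0.828320991143119	0.137349576798733	0.131447253574152
ct_marker_034	0.0740686188125983	0.0736867044167593	0.0763456637575291	0.876454848679714	0.101399544999003	0.13181554462295
ct_marker_035	0.0993085770541802	0.143964448373299	0.0875125378812663	0.871611931920052	0.156619365040679	0.147934818593785
ct_marker_036	0.160113170973491	0.124355232995003	0.153822065487038	0.8265361700207	0.171153680563439	0.100554796569049
ct_marker_037	0.114749897345901	0.12020473376615	0.111765759401023	0.842092076712288	0.128822518636007	0.131329021169804
ct_marker_038	0.152776124558877	0.0961431640037335	0.150200336310081	0.817160545324441	0.103347707991488	0.0826017702533864
ct_marker_039	0.159000303356443	0.157131938966922	0.178998613180593	0.911036131693982	0.159611116291489	0.0536075265309773
ct_marker_040	0.109397502432112	0.0741977789578959	0.155442939470522	0.874493048735894	0.0965853061783128	0.0921167632355355
ct_marker_041	0.153931855908595	0.101528696094174	0.132425821723882	0.0935449302592315	0.946772172884084	0.0512535679154098
ct_marker_042	0.099652597962413	0.113207934023812	0.159981336833444	0.134825307200663	0.897677780222148	0.107000268197153
ct_marker_043	0.148761160094291	0.11460231728619	0.115220323437825	0.137991336022969	0.920868758042343	0.139102513748221
ct_marker_044	0.106780828281771	0.100315254505258	0.136217940852512	0.145471921812277	0.936702886153944	0.0743417483195662
ct_marker_045	0.16754830369493	0.133622181969695	0.116515197949484	0.146271753250621	0.873509536858182	0.164491951607633
ct_marker_046	0.0915395388030447	0.0946979320724495	0.118202963329386	0.0814854598348029	0.807031481899321	0.111408676253632
ct_marker_047	0.060733982056845	0.174293530818541	0.0951104393787682	0.144844853940886	0.908893763797823	0.0627457318780944
ct_marker_048	0.156117580318823	0.0555525263980962	0.155200671986677	0.0835423727566376	0.814782809955068	0.101265264418907
ct_marker_049	0.166801908686757	0.14950036152266	0.0778167484817095	0.0743028193642385	0.93321486209752	0.145027120292652
ct_marker_050	0.175644531706348	0.0764901055418886	0.104991804570891	0.167636909494177	0.858965926757082	0.13934959971346
ct_marker_051	0.124498954794835	0.139018093405757	0.0990923617081717	0.172030062729027	0.111286795497872	0.817953689862043
ct_marker_052	0.143610334545374	0.101501807954628	0.152004575221799	0.17574579884531	0.111875038596336	0.924160094419494
ct_marker_053	0.150627621142194	0.0575992717593908	0.0974039258924313	0.0639310467918403	0.074312700862065	0.840672430000268
ct_marker_054	0.13160890406929	0.145713016109075	0.145110594669823	0.10027707958594	0.0949814106873237	0.942696622607764
ct_marker_055	0.143988614392001	0.131230819209013	0.0994432275090367	0.162460858516861	0.139244533397723	0.897607863484882
ct_marker_056	0.100288066258654	0.131791923367418	0.142928064924199	0.101280805696733	0.144117580670863	0.820879483514
ct_marker_057	0.0711628011218272	0.123569360605907	0.0548175730509683	0.158828234015964	0.132323639886454	0.812132822093554
ct_marker_058	0.0743396768392995	0.152611665769946	0.114812687793747	0.0567489166394807	0.0564051620895043	0.867710005189292
ct_marker_059	0.100862431637943	0.0739310114481486	0.143793748628814	0.130542888354976	0.0676954431412742	0.933667594322469
ct_marker_060	0.0856071572611108	0.158249497213401	0.177207340043969	0.118661406356841	0.122780110309832	0.918159731128253
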