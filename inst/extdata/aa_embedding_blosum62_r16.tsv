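# aa_embedding dim=16 seed=42 stress=0.007031711328447484 scale=0.89596590036113555 matrix=4-BLOSUM62
A	-0.220010392672309041	 1.621324679995931994	-1.467789818077119834	 0.947986344663339642	 0.230380672640737832	 0.126591375471357348	-1.367634149934312093	 1.287727915755257024	-0.936377456723810342	 0.077621208697605526	 0.641450386270847495	-0.182494175791013263	-0.033260316806367769	 0.061904847846205535	 0.074685788078592052	 0.016911838480297741
R	 1.529722733531004630	-0.534410452080730791	 1.699027346869534494	 1.778518780962364154	-1.112887364593510675	-0.014479594152269964	-0.776633639613470983	-0.159718020091435930	-0.476864428053355327	 0.254990305533022377	-1.068485087811506418	-0.748065480255720283	 0.399548041462924386	-0.031605003841003690	-0.054214111532675427	-0.010146002791060468
N	 2.2774733762307310947	-0.3744885771182738243	-0.2768017069179529166	-0.9633878070231820523	-1.6534322287957929909	 0.1659492055020262702	 0.2553229878043590806	-1.4488683007817442228	 0.2110874575045594004	-0.6273211139534226044	-0.0251203127268353199	 0.4964503154238734672	-0.3305731100105544495	 0.0262027667830860879	 0.0290142979333030716	 0.0056664616280765866
D	 2.34600627181399667975	 0.18655502214534830374	-0.48351455646856789095	-2.20850034848753518091	 0.54170516408875479808	 0.23967340186269656122	 1.27672316580606626246	 0.79215306661824480550	 0.67652719104222558411	 0.50387002459159269119	-0.74836745442403229678	-0.47963343248389828100	-0.42125903986880686158	 0.03370134168387591694	 0.04377257303115100057	 0.00099969509696521699
C	-1.846547187969039383	 1.158950581176654282	-1.878165195775785445	 0.843964488885900033	-0.706150435905768425	-2.286585521150355405	 0.537569542531305622	 1.055561103040002280	 0.574882728741764937	-0.097711695017873773	-0.898532447397888623	 0.483913218475215456	-0.214666776826174827	 0.018681355366040417	 0.031461636599527387	-0.016846797903063076
Q	 1.6044672511324764574	-0.6244748805160248439	 1.5919832584977560153	 0.7243042519283711123	 0.7919044653714807369	 0.0435828907387201953	 0.6878871111882590705	 0.7168166018105261994	 0.5326200370081273228	-1.0629144699801074125	 1.0213315126758726326	-0.1087530658945364825	-0.3426981488747479210	-0.0319510574825699611	-0.0704485904471399693	 0.0081091034139938786
E	 2.346589464802500302	-0.267310117350601062	 1.199575537294898409	-0.820451892615007838	 1.073882478560886478	 0.535202065928665149	 0.799990234390451027	 1.474602426291397927	-0.208939809865166859	-0.027591924676530828	-0.271119560579341445	-0.178723817776410276	-0.224983599584586441	 0.035899995094404835	 0.036176265620019230	-0.020087287545050056
G	 1.6683082962223108048	-0.0831819040089999823	-2.9525647589789021374	 0.7113730254127998975	 0.2017039171722641022	 1.8453845714391594601	-1.2864269345127525845	-0.6172472006381732879	 0.5601048984156502542	-0.6507942964004868047	-0.3596733844312143269	-0.0331184409577417460	-0.3585904280452046344	-0.0111432593512375382	-0.0473695714974565821	 0.0070937735179935832
H	 1.16645352934488655272	-2.33474155933220561820	 0.48320175042264440490	-1.04789446465556457255	-1.15783802082748721318	-1.35149760982876343540	-1.72517367395693987930	 0.25903020307391494415	-0.05341560719021647835	-0.54492424521148363770	 0.45081684120920362258	-0.08074704442757014988	-0.02656860179125272725	 0.06087122309649749957	 0.08162644993217621492	 0.00094367987155893516
I	-2.92885385093699924	 1.55079691272358411	 0.91871047120745541	-1.73227025313728644	-0.30617569857081162	 0.39100161947921636	-0.46397275413946465	-0.17462753708608050	 0.14329535616998476	-0.34604961787280547	-0.54073395200288132	-0.33788709587076221	 0.98271778287428335	-0.11513960705151804	-0.15145280219221788	-0.01987831564402525
L	-2.812136532720781013	 1.009313302969705228	 1.523766127988236629	 0.138425343565475034	-0.661691348338701135	 0.329235548423808644	-0.031427496938566800	-0.382333607998570801	 0.212437614501111732	 0.432662090076216754	 0.182254310253450624	-0.758542108610423149	-1.881514115012241195	 0.065242897696583729	 0.036976188566290501	-0.015087773711713850
K	 2.0638952521370730331	 0.1400920280771333348	 1.6709692816992545161	 1.6109551162943358538	-0.3357298888173524953	 0.1244693214791284253	-0.0318919337176781503	 0.0949535501349475508	-0.3593260871536055334	 0.9479798927079430282	-0.9919730066749868902	 1.4371553907065159894	 0.5083933738541493996	-0.0023269012908864826	-0.0125369475557643890	-0.0058452876434106063
M	-1.885423384997245266	 0.584367684674688137	 1.241176443988311506	 0.910473490920272743	-0.092868280493359504	 0.906060452568119512	 0.828748081437019057	-0.534753609233236671	 1.665261797079884420	-0.353806055855249602	 0.711813040066961111	 0.394800503371985578	 0.805318632928253342	 0.040031707563762862	 0.118351229850186701	 0.051122949452229671
F	-2.695815006829325178	-2.333259879504381296	-0.682362285006749447	-0.914700521763701091	 0.124693809256035043	 0.588459604160440852	-0.369382177047423821	 0.027637379384143804	-0.168210815676328812	 1.513636498350877657	-0.092171143236325775	 0.079064676625432539	-0.026774506964067003	 0.042189284653210368	 0.058163892188375754	 0.033877764210489540
P	 1.6504745271047405186	 1.5276277703879923564	-0.0511072851289507482	 0.1740803076233547186	 2.6995928305550846993	-1.6936149675121754399	-0.8115550090845238262	-1.7336430031294507437	 0.3767635999774263666	 0.9710116498714347344	-0.1301287277812273602	-0.2944669641642272961	-0.0376207512818314341	-0.0115714873424742105	-0.0076780810165944218	-0.0033166695891780180
S	 1.557877088363135210	 1.024684420541299046	-1.377784334270980571	 0.053046211553416996	-1.210987171046591371	-0.136270290645248926	 0.645801974043208826	 0.344428674166682880	 0.222794809775813590	 0.863706144330875669	 1.983331901135621855	 0.087220819761620716	 0.645478375824185657	-0.068689387697576931	-0.118589543962330679	-0.015133268607642717
T	 0.1813017928297008807	 1.7221250532337799566	-0.5570648437085805593	 0.0037190900937185338	-0.7131826137642131025	-0.1000419517868984948	 1.6536088027233535325	-1.0709180859037508160	-2.2357544241836522225	-0.1296829242205992661	 0.5348405380159561018	-0.3086408859009853733	 0.1707098755090911690	 0.0156236974103254236	 0.0240806041544856797	 0.0279432892617908421
W	-1.855950981790528642	-3.065432417779187624	-1.255088729322359598	 1.338339303110310796	 1.213825518961317629	 0.094149314962284514	 1.769624146728213443	-0.084727039214342340	-0.096179123894941598	-0.131234813482346890	-0.425584326739916752	-0.300676328335224952	 0.358448481323701940	-0.061898712862306277	-0.041104332230610455	-0.019850153539680483
Y	-1.792162290971682781	-2.969091818203534405	-0.015192466476556650	-0.720037629012230229	 0.312904630292031860	-0.782059383968718325	-0.914106487787714417	-0.087216773708770859	-0.394939061420982451	-0.159667124676784122	 0.352755208677076659	 0.269609234246173168	-0.062014892234414344	-0.058744264948054091	-0.102539303176474986	-0.035141745574050837
V	-2.3556699546246364640	 2.0605541499678214912	 0.6690257621644121189	-0.8279428383191408392	 0.7603495642549858990	 0.9747899470287834101	-0.6770717899193938738	 0.2411422575104269495	-0.2457686760544935400	-1.4337795328118738691	-0.3267043344988268538	 0.5635346818577291472	 0.0899097235236665793	 0.0271113232735121952	 0.0230644757932860905	 0.0085015525767710917
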